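test_that("one-tailed Welch t matches the closed-form computation", {
  a <- c(5, 6, 7, 8)
  b <- c(1, 2, 3, 4)
  r <- one_tailed_t(a, b)
  expect_equal(r$direction, "higher_in_ASE")
  expect_equal(r$p_raw, welch_one_tailed_p(a, b), tolerance = 1e-10)
  r2 <- one_tailed_t(b, a)
  expect_equal(r2$direction, "higher_in_CNE")
  expect_equal(r2$p_raw, welch_one_tailed_p(b, a), tolerance = 1e-10)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    r <- one_tailed_t(x, y)
    expect_equal(r$p_raw, welch_one_tailed_p(x, y), tolerance = 1e-10)
    expect_equal(r$direction,
                 if (mean(x) > mean(y)) "higher_in_ASE" else "higher_in_CNE")
  }
})

test_that("degenerate and tie inputs follow the documented conventions", {
  r <- one_tailed_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_raw, 0.5)
  expect_equal(r$direction, "higher_in_CNE")
  r2 <- one_tailed_t(c(2, 2, 2), c(2, 2, 2))
  expect_true(r2$degenerate)
  expect_equal(r2$p_raw, 0.5)
  expect_error(one_tailed_t(1, c(1, 2)), "insufficient")
  r3 <- one_tailed_t(c(5, 5, 5), c(1, 1, 1))
  expect_equal(r3$direction, "higher_in_ASE")
  expect_true(r3$p_raw > 0 && r3$p_raw < 1e-100)
})

test_that("bonferroni caps at one and significance is strict", {
  expect_equal(bonferroni(0.001, 20), 0.02)
  expect_equal(bonferroni(0.2, 10), 1.0)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.1, 0), "m")
  expect_true(significance_call(0.009))
  expect_false(significance_call(0.01))   # strictly smaller than alpha
  expect_false(significance_call(1.0))
})

test_that("corrections implement subtraction and pseudocount division", {
  expect_equal(correct_input(10, 3), 7)
  expect_equal(correct_input(2, 5), -3)   # negatives preserved
  expect_equal(correct_nucleosome(10, 2, 1e-9), 5, tolerance = 1e-8)
  expect_equal(correct_nucleosome(10, 0, 1), 10)
  expect_error(correct_nucleosome(1, 1, 0), "pseudocount")
})

make_levels <- function(values_by_cell) {
  # values_by_cell: named list "<type>|<bin>" -> numeric observations
  rbindlist(lapply(names(values_by_cell), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- values_by_cell[[key]]
    data.table(site_id = sprintf("%s.s%d", parts[1], seq_along(v)),
               event_id = sprintf("%s.s%d", parts[1], seq_along(v)),
               event_type = parts[1], chrom = "c", strand = "+",
               kind = sub("_.*", "", parts[2]), bin = parts[2],
               start = 0, end = 100, exon_ordinal = 2L,
               feature = parts[3] %||% "F", cell_line = "c1",
               value = v, missing = FALSE)
  }))
}
`%||%` <- function(x, y) if (is.na(x) || is.null(x)) y else x

test_that("pooling cell lines sharpens a consistent signal", {
  set.seed(41)
  ase <- rnorm(40, mean = 1)
  cne <- rnorm(40, mean = 0)
  one_line <- one_tailed_t(ase, cne)
  pooled <- one_tailed_t(rep(ase, 2), rep(cne, 2))
  expect_lt(pooled$p_raw, one_line$p_raw)
})

test_that("test_associations tests every populated cell against CNE", {
  lv <- make_levels(list(
    "ES|acceptor_exonic|F" = c(5, 6, 7, 8),
    "CNE|acceptor_exonic|F" = c(1, 2, 3, 4)))
  res <- test_associations(lv)
  expect_equal(nrow(res), 1L)
  expect_equal(res$direction, "higher_in_ASE")
  expect_equal(res$p_raw, welch_one_tailed_p(c(5, 6, 7, 8), c(1, 2, 3, 4)),
               tolerance = 1e-10)
  expect_equal(res$p_adj, res$p_raw)  # family of one
  expect_error(test_associations(lv[event_type != "CNE"]), "CNE")
})

test_that("a constant nucleosome track leaves p-values unchanged", {
  set.seed(52)
  lv <- make_levels(list(
    "ES|acceptor_exonic|F" = rpois(30, 30),
    "CNE|acceptor_exonic|F" = rpois(30, 20),
    "ES|donor_exonic|F" = rpois(30, 25),
    "CNE|donor_exonic|F" = rpois(30, 25)))
  ref <- copy(lv)[, value := 7]
  corrected <- apply_correction(lv, ref, mode = "nucleosome_divide",
                                pseudocount = 1)
  r0 <- test_associations(lv)
  r1 <- test_associations(corrected)
  expect_equal(r1$p_raw, r0$p_raw, tolerance = 1e-10)
  expect_equal(r1$direction, r0$direction)
})

test_that("a zero input track makes input correction the identity", {
  set.seed(53)
  lv <- make_levels(list(
    "ES|acceptor_exonic|F" = rpois(20, 30),
    "CNE|acceptor_exonic|F" = rpois(20, 20)))
  ref <- copy(lv)[, value := 0]
  corrected <- apply_correction(lv, ref, mode = "input_subtract")
  expect_equal(corrected$value, lv$value)
  expect_identical(apply_correction(lv, ref, mode = "none"), lv)
})

test_that("missing input for a cell line is a configuration error", {
  lv <- make_levels(list("ES|acceptor_exonic|F" = c(1, 2),
                         "CNE|acceptor_exonic|F" = c(1, 2)))
  ref <- copy(lv)[1:2][, value := 0]
  expect_error(apply_correction(lv, ref, mode = "input_subtract"), "missing")
})

test_that("signed log-p matrix encodes direction in the sign", {
  res <- data.table(
    feature = "F", event_type = c("ES", "ME", "A3SS"),
    bin = "acceptor_exonic", n_ase = 10L, n_cne = 10L,
    mean_ase = c(2, 1, 1), mean_cne = c(1, 2, 1),
    direction = c("higher_in_ASE", "higher_in_CNE", "higher_in_CNE"),
    p_raw = c(0.001, 0.001, 1), degenerate = FALSE,
    p_adj = c(0.001, 0.001, 1), significant = c(TRUE, TRUE, FALSE))
  m <- build_matrix(res)
  expect_equal(dim(m), c(1L, 20L))
  expect_equal(m["F", "ES.acceptor_exonic"], 3)
  expect_equal(m["F", "ME.acceptor_exonic"], -3)
  expect_equal(m["F", "A3SS.acceptor_exonic"], 0)
  expect_true(is.na(m["F", "IR.acceptor_exonic"]))
  # sign <-> direction bijection over populated, non-boundary cells
  for (i in which(res$p_adj < 1)) {
    cell <- m[res$feature[i], paste(res$event_type[i], res$bin[i], sep = ".")]
    expect_equal(sign(cell),
                 if (res$direction[i] == "higher_in_ASE") 1 else -1)
  }
  # duplicate cells are rejected
  expect_error(build_matrix(rbind(res, res[1])), "duplicate")
})
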