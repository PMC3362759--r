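small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed,
             n_per_type = c(ES = 3, ME = 3, A3SS = 3, A5SS = 3, IR = 3),
             n_cne = 3, ...)
}

test_that("the constructive fixture is recovered exactly by annotation", {
  sim <- generate_genes(small_cfg())
  ev <- filter_positional(annotate_genes(sim$genes), sim$genes)
  counts <- table(factor(ev$event_type,
                         levels = c("ES", "ME", "A3SS", "A5SS", "IR", "CNE")))
  expect_equal(unname(c(counts)), rep(3L, 6))
  got <- unique(select_splice_sites(ev)[, .(event_type, kind, pos)])
  want <- unique(sim$truth$sites[filtered == FALSE, .(event_type, kind, pos)])
  setkey(got, event_type, kind, pos)
  setkey(want, event_type, kind, pos)
  expect_identical(got, want)
})

test_that("zero-gene configs give empty outputs", {
  cfg <- sim_config(seed = 1, n_per_type = c(ES = 0, ME = 0, A3SS = 0,
                                             A5SS = 0, IR = 0), n_cne = 0)
  sim <- generate_genes(cfg)
  expect_length(sim$genes, 0L)
  expect_equal(sum(Biostrings::width(sim$genome)), 0L)
  expect_equal(nrow(generate_reads(sim, "F", seed = 1)), 0L)
})

test_that("identical seeds give byte-identical fixtures", {
  d1 <- file.path(tempdir(), "fixA")
  d2 <- file.path(tempdir(), "fixB")
  cfg <- small_cfg(seed = 12,
                   effects = data.frame(feature = "F1", event_type = "ES",
                                        multiplier = 1.5))
  generate_fixture(cfg, d1)
  generate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every planted effect is recorded in the truth table", {
  eff <- data.frame(feature = c("F1", "F1", "F2"),
                    event_type = c("ES", "IR", "A5SS"),
                    multiplier = c(0.5, 2, 1.5))
  sim <- generate_genes(small_cfg(seed = 3, effects = eff, features = "F3"))
  tt <- sim$truth$effects
  expect_equal(nrow(tt), 3 * 5)  # all features x all types
  for (r in seq_len(nrow(eff))) {
    expect_equal(tt[feature == eff$feature[r] &
                      event_type == eff$event_type[r], multiplier],
                 eff$multiplier[r])
  }
  expect_true(all(tt[feature == "F3", multiplier] == 1))
  expect_equal(tt$direction,
               ifelse(tt$multiplier > 1, "higher_in_ASE",
                      ifelse(tt$multiplier < 1, "higher_in_CNE", "null")))
})

test_that("read rates follow the planted multipliers (Poisson means)", {
  cfg <- sim_config(seed = 8,
                    n_per_type = c(ES = 40, ME = 0, A3SS = 40, A5SS = 0,
                                   IR = 0),
                    n_cne = 40,
                    effects = data.frame(feature = "F", event_type = "A3SS",
                                         multiplier = 1.5))
  sim <- generate_genes(cfg)
  ev <- filter_positional(annotate_genes(sim$genes), sim$genes)
  sites <- select_splice_sites(ev)
  tr <- prepare_reads(generate_reads(sim, "F", seed = 99), extension = 0)
  # count read *starts* per exonic bin: lambda x 100 = 20 at baseline
  bins <- make_bins(sites)
  starts_in <- function(b) {
    sum(tr$reads$start >= b$start & tr$reads$start < b$end)
  }
  mean_for <- function(type) {
    bb <- bins[bins$event_type == type & bins$side == "exonic", ]
    mean(vapply(seq_len(nrow(bb)), function(i) starts_in(bb[i]), numeric(1)))
  }
  expect_equal(mean_for("CNE"), 20, tolerance = 0.12)
  expect_equal(mean_for("A3SS"), 30, tolerance = 0.12)
  expect_equal(mean_for("ES"), 20, tolerance = 0.12)
})

test_that("methylome honors baseline and per-type probabilities", {
  cfg0 <- small_cfg(seed = 6, meth_baseline = 0)
  sim0 <- generate_genes(cfg0)
  m0 <- generate_methylome(sim0, seed = 1)
  expect_true(all(m0$methylated == 0))
  cfg1 <- small_cfg(seed = 6, meth_baseline = 1)
  m1 <- generate_methylome(generate_genes(cfg1), seed = 1)
  expect_true(all(m1$methylated == 1))
  expect_equal(m1$pos, track_sequence(sim0$genome)$cpg[["chrS"]])

  # planted hypomethylation around ES splice sites
  cfg <- sim_config(seed = 9,
                    n_per_type = c(ES = 60, ME = 0, A3SS = 0, A5SS = 0,
                                   IR = 0),
                    n_cne = 60, meth_baseline = 0.6,
                    meth_effects = c(ES = 0.3))
  sim <- generate_genes(cfg)
  meth <- generate_methylome(sim, seed = 2)
  es_sites <- sim$truth$sites[event_type == "ES"]
  near <- rep(FALSE, nrow(meth))
  for (i in seq_len(nrow(es_sites))) {
    near <- near | (meth$pos >= es_sites$pos[i] - 500 &
                      meth$pos < es_sites$pos[i] + 500)
  }
  expect_equal(mean(meth$methylated[near]), 0.3, tolerance = 0.1)
  expect_equal(mean(meth$methylated[!near]), 0.6, tolerance = 0.05)
})

test_that("planted methylation effects propagate to a significant call", {
  cfg <- sim_config(seed = 14,
                    n_per_type = c(ES = 80, ME = 0, A3SS = 0, A5SS = 0,
                                   IR = 0),
                    n_cne = 80, meth_baseline = 0.6,
                    meth_effects = c(ES = 0.3))
  sim <- generate_genes(cfg)
  ev <- filter_positional(annotate_genes(sim$genes), sim$genes)
  sites <- select_splice_sites(ev)
  meth <- generate_methylome(sim, seed = 4)
  track <- track_methylation(meth[, .(chrom, pos, methylated)])
  lv <- collect_levels(sites, list(mCG = list(combined = track)))
  res <- test_associations(lv)
  es <- res[event_type == "ES"]
  expect_true(all(es$direction == "higher_in_CNE"))
  expect_true(all(es$significant))
})

test_that("a deliberately near-TSS gene is removed by the positional filter", {
  cfg <- small_cfg(seed = 4, n_near_tss = 1)
  sim <- generate_genes(cfg)
  ev <- annotate_genes(sim$genes)
  kept <- filter_positional(ev, sim$genes)
  tss_gene <- sim$truth$genes[filtered == TRUE, gene_id]
  expect_length(tss_gene, 1L)
  expect_true(tss_gene %in% ev$gene_id)       # annotated before filtering
  expect_false(tss_gene %in% kept$gene_id)    # gone afterwards
})
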