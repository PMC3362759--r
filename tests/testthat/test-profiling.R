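site_row <- function(kind, pos, strand = "+", id = "e1.1") {
  data.table(site_id = id, event_id = sub("\\.\\d+$", "", id),
             event_type = "ES", gene_id = "g", chrom = "chrR",
             strand = strand, kind = kind, pos = pos, exon_ordinal = 2L)
}

test_that("bins sit on the correct side of the boundary for each strand", {
  b <- make_bins(site_row("acceptor", 5000, "+"))
  expect_equal(b[b$side == "intronic", c(start, end)], c(4900, 5000))
  expect_equal(b[b$side == "exonic", c(start, end)], c(5000, 5100))
  b <- make_bins(site_row("acceptor", 5000, "-"))
  expect_equal(b[b$side == "exonic", c(start, end)], c(4900, 5000))
  expect_equal(b[b$side == "intronic", c(start, end)], c(5000, 5100))
  b <- make_bins(site_row("donor", 5000, "+"))
  expect_equal(b[b$side == "exonic", c(start, end)], c(4900, 5000))
  b <- make_bins(site_row("donor", 5000, "-"))
  expect_equal(b[b$side == "exonic", c(start, end)], c(5000, 5100))
  # the robustness-check bin width is just a parameter
  b50 <- make_bins(site_row("acceptor", 5000, "+"), bin_length = 50)
  expect_equal(b50[b50$side == "intronic", c(start, end)], c(4950, 5000))
})

test_that("exonic bins fall inside the event exon, intronic bins outside", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_per_type = c(ES = 4, ME = 4, A3SS = 4,
                                              A5SS = 4, IR = 4), n_cne = 4)
  sim <- generate_genes(cfg)
  ev <- filter_positional(annotate_genes(sim$genes), sim$genes)
  sites <- select_splice_sites(ev)
  bins <- make_bins(sites)
  exons <- rbindlist(lapply(sim$genes, function(g) {
    rbindlist(lapply(g$transcripts, function(t) {
      data.table(s = t$exons[, "start"], e = t$exons[, "end"])
    }))
  }))
  for (i in which(bins$event_type != "IR")) {
    inside <- any(exons$s <= bins$start[i] & exons$e >= bins$end[i])
    if (bins$side[i] == "exonic") {
      expect_true(inside, label = sprintf("exonic bin %d inside an exon", i))
    }
  }
  # intronic acceptor/donor bins of ES exons avoid the event exon itself
  es <- bins[bins$event_type == "ES" & bins$side == "intronic", ]
  ev_es <- ev[ev$event_type == "ES", ]
  for (i in seq_len(nrow(es))) {
    exon <- ev_es[ev_es$event_id == es$event_id[i], ]
    expect_false(es$start[i] < exon$exon_end && exon$exon_start < es$end[i])
  }
})

test_that("collect_levels emits one observation per site, bin, feature, line", {
  sites <- rbind(site_row("acceptor", 1000), site_row("donor", 1147, id = "e1.2"))
  raw <- data.table(chrom = "chrR", start = c(900, 1100), end = c(936, 1136),
                    strand = "+")
  tracks <- list(F = list(c1 = prepare_reads(copy(raw)),
                          c2 = prepare_reads(copy(raw))))
  lv <- collect_levels(sites, tracks)
  expect_equal(nrow(lv), 2 * 2 * 2)  # 2 sites x 2 bins x 2 lines
  expect_setequal(unique(lv$bin),
                  c("acceptor_intronic", "acceptor_exonic",
                    "donor_exonic", "donor_intronic"))
  # every value equals the corresponding direct query
  for (i in seq_len(nrow(lv))) {
    b <- make_bins(sites[sites$site_id == lv$site_id[i], ])
    b <- b[b$bin == lv$bin[i], ]
    expect_equal(lv$value[i],
                 region_read_count(tracks$F[[lv$cell_line[i]]], "chrR",
                                   b$start, b$end))
  }
})

test_that("methylation bins without CpG sites are flagged missing", {
  sites <- site_row("acceptor", 1000)
  meth <- track_methylation(data.table(chrom = "chrR", pos = 950,
                                       methylated = TRUE))
  lv <- collect_levels(sites, list(mCG = list(x = meth)))
  expect_true(lv$missing[lv$bin == "acceptor_exonic"])   # no CpG in [1000,1100)
  expect_false(lv$missing[lv$bin == "acceptor_intronic"]) # site 950 inside
  expect_true(is.na(lv$value[lv$missing]))
})

test_that("position profiles have the documented window and orientation", {
  raw <- data.table(chrom = "chrR", start = 1000, end = 1036, strand = "+")
  tr <- prepare_reads(copy(raw))  # extended to (1000, 1200)
  prof <- position_profile(site_row("acceptor", 1000, "+"), tr, "acceptor")
  expect_equal(nrow(prof), 701L)
  expect_equal(prof$offset, -500:200)
  expect_equal(prof$value[prof$offset %in% 0:199], rep(1, 200))
  expect_equal(prof$value[prof$offset < 0], rep(0, 500))

  # a minus-strand site with the mirrored read gives the identical profile
  raw_m <- data.table(chrom = "chrR", start = 964, end = 1000, strand = "-")
  tr_m <- prepare_reads(copy(raw_m))  # extended to (800, 1000)
  prof_m <- position_profile(site_row("acceptor", 1000, "-"), tr_m, "acceptor")
  expect_equal(prof_m$value, prof$value)

  # mean of identical sites equals either one
  two <- rbind(site_row("acceptor", 1000, "+", "e1.1"),
               site_row("acceptor", 1000, "+", "e2.1"))
  expect_equal(position_profile(two, tr, "acceptor")$value, prof$value)
})

test_that("mixed-strand profiles equal extract-flip-average by hand", {
  set.seed(55)
  raw <- random_reads(800, 6000)
  tr <- prepare_reads(copy(raw))
  ext <- naive_extend(raw)
  sites <- rbind(site_row("donor", 2000, "+", "e1.1"),
                 site_row("donor", 3000, "-", "e2.1"),
                 site_row("donor", 4000, "+", "e3.1"))
  prof <- position_profile(sites, tr, "donor")
  offs <- -200:500
  oracle <- rowMeans(cbind(
    naive_coverage(ext, 2000 - 200, 2000 + 501),
    rev(naive_coverage(ext, 3000 - 501, 3000 + 200)),
    naive_coverage(ext, 4000 - 200, 4000 + 501)))
  expect_equal(prof$value, oracle)
})

test_that("read profile over the exonic bin matches the bin-level aggregate", {
  set.seed(66)
  raw <- random_reads(1500, 8000)
  tr <- prepare_reads(copy(raw))
  sites <- rbind(site_row("acceptor", 3000, "+", "e1.1"),
                 site_row("acceptor", 5000, "-", "e2.1"))
  prof <- position_profile(sites, tr, "acceptor")
  lv <- collect_levels(sites, list(F = list(c1 = tr)))
  exonic <- lv[lv$bin == "acceptor_exonic", ]
  # per-position coverage summed over the bin >= read count (reads overlap
  # several positions); the two aggregation paths agree on ordering of sites
  cov_mean <- mean(prof$value[prof$offset %in% 0:99])
  expect_gte(cov_mean * 100, mean(exonic$value))
})

test_that("smoothing is a truncated centered moving average", {
  expect_equal(smooth_profile(rep(3.5, 50), window = 7), rep(3.5, 50))
  x <- c(rep(0, 200), 1, rep(0, 200))
  sm <- smooth_profile(x, window = 147)
  expect_equal(sum(sm > 0), 147L)
  expect_equal(max(sm), 1 / 147)
  expect_error(smooth_profile(1:10, window = 0), "window")
  expect_error(smooth_profile(1:10, window = 4), "odd")
  set.seed(3)
  for (w in c(3, 7, 147)) {
    x <- rnorm(300)
    expect_equal(smooth_profile(x, window = w), naive_moving_average(x, w),
                 tolerance = 1e-12)
  }
})

test_that("stratification by exon ordinal conserves observations", {
  set.seed(21)
  cfg <- sim_config(seed = 21, n_per_type = c(ES = 5, ME = 5, A3SS = 5,
                                              A5SS = 5, IR = 5), n_cne = 5)
  sim <- generate_genes(cfg)
  ev <- annotate_genes(sim$genes)
  strata <- stratify_by_ordinal(ev, c(2, 3, 4))
  expect_true(all(names(strata) %in% c("2", "3", "4")))
  total <- sum(vapply(strata, nrow, integer(1)))
  expect_equal(total, nrow(ev[ev$exon_ordinal %in% 2:4, ]))
  # requesting an absent ordinal drops it silently (logged)
  expect_false("9" %in% names(stratify_by_ordinal(ev, c(2, 9))))
})
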