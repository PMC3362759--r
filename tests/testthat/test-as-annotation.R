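mk_tx <- function(id, exons, strand = "+", gid = "g") {
  new_transcript(id, gid, "chr1", strand, exons)
}

test_that("textbook configurations classify as ES, ME, A3SS, A5SS, IR", {
  tA <- mk_tx("a", cbind(c(100, 300, 500), c(200, 400, 600)))
  tB <- mk_tx("b", cbind(c(100, 500), c(200, 600)))
  es <- classify_pairwise(tA, tB)
  expect_equal(es$event_type, "ES")
  expect_equal(c(es$exon_start, es$exon_end), c(300, 400))

  tA <- mk_tx("a", cbind(c(100, 300, 700), c(200, 400, 800)))
  tB <- mk_tx("b", cbind(c(100, 500, 700), c(200, 600, 800)))
  me <- classify_pairwise(tA, tB)
  expect_equal(me$event_type, "ME")
  expect_equal(c(me$exon_start, me$exon_end, me$exon2_start, me$exon2_end),
               c(300, 400, 500, 600))

  tA <- mk_tx("a", cbind(c(100, 300, 700), c(200, 500, 800)))
  tB <- mk_tx("b", cbind(c(100, 350, 700), c(200, 500, 800)))
  a3 <- classify_pairwise(tA, tB)
  expect_equal(a3$event_type, "A3SS")
  expect_setequal(c(a3$exon_start, a3$exon2_start), c(300, 350))
  # same geometry on the minus strand is an A5SS (donor side differs)
  a5 <- classify_pairwise(mk_tx("a", cbind(c(100, 300, 700), c(200, 500, 800)), "-"),
                          mk_tx("b", cbind(c(100, 350, 700), c(200, 500, 800)), "-"))
  expect_equal(a5$event_type, "A5SS")

  tA <- mk_tx("a", cbind(c(100, 300, 500, 700), c(200, 400, 600, 800)))
  tB <- mk_tx("b", cbind(c(100, 300, 700), c(200, 600, 800)))
  ir <- classify_pairwise(tA, tB)
  expect_equal(ir$event_type, "IR")
  expect_equal(c(ir$intron_start, ir$intron_end), c(400, 500))
})

test_that("pairwise classification equals the brute-force oracle on random genes", {
  set.seed(2024)
  for (i in 1:200) {
    g <- random_gene(sprintf("g%d", i), n_tx = 2)
    impl <- impl_event_keys(classify_pairwise(g$transcripts[[1]],
                                              g$transcripts[[2]]))
    expect_identical(impl, oracle_classify(g), label = sprintf("gene %d", i))
  }
})

test_that("annotate_gene de-duplicates events discovered from several pairs", {
  # the same skipped exon is discoverable against two skipping partners
  tA <- mk_tx("a", cbind(c(100, 300, 500), c(200, 400, 600)))
  tB <- mk_tx("b", cbind(c(100, 500), c(200, 600)))
  tC <- mk_tx("c", cbind(c(100, 500), c(200, 600)))
  ev <- annotate_gene(new_gene("g", "chr1", "+", list(tA, tB, tC)))
  expect_equal(sum(ev$event_type == "ES"), 1L)
})

test_that("single-transcript genes contribute their internal exons as CNE", {
  g <- new_gene("g", "chr1", "+", list(
    mk_tx("a", cbind(c(100, 300, 500), c(200, 400, 600)))))
  ev <- annotate_gene(g)
  expect_equal(ev$event_type, "CNE")
  expect_equal(c(ev$exon_start, ev$exon_end), c(300, 400))
})

test_that("annotation is invariant to transcript input order", {
  set.seed(99)
  for (i in 1:25) {
    g <- random_gene(sprintf("g%d", i), n_tx = 3)
    ev1 <- annotate_gene(g)
    perm <- new_gene(g$gene_id, g$chrom, g$strand, rev(g$transcripts))
    ev2 <- annotate_gene(perm)
    cols <- c("event_type", "exon_start", "exon_end", "site_key")
    expect_identical(ev1[, cols, with = FALSE], ev2[, cols, with = FALSE])
  }
})

test_that("CNE and ASE site tuples are disjoint and sites exist in transcripts", {
  set.seed(123)
  for (i in 1:100) {
    g <- random_gene(sprintf("g%d", i))
    ev <- annotate_gene(g)
    cne_keys <- sub("^CNE:", "", ev$site_key[ev$event_type == "CNE"])
    ase_keys <- sub("^[^:]+:", "", ev$site_key[ev$event_type != "CNE"])
    expect_length(intersect(cne_keys, ase_keys), 0L)
    if (nrow(ev)) {
      bounds <- unlist(lapply(g$transcripts, function(t) t$exons))
      sites <- select_splice_sites(ev)
      expect_true(all(sites$pos %in% bounds))
    }
  }
})

test_that("positional filter removes exons near transcript ends", {
  # transcript spans 0..10000; internal exon at 1500 is inside the window
  near <- new_gene("g1", "chr1", "+", list(
    mk_tx("a", cbind(c(0, 1500, 8000), c(100, 1650, 10000)), gid = "g1"),
    mk_tx("b", cbind(c(0, 8000), c(100, 10000)), gid = "g1")))
  far <- new_gene("g2", "chr1", "+", list(
    mk_tx("a", cbind(c(0, 2500, 8000), c(2100, 2650, 10000)), gid = "g2"),
    mk_tx("b", cbind(c(0, 8000), c(2100, 10000)), gid = "g2")))
  ev <- annotate_genes(list(near, far))
  kept <- filter_positional(ev, list(near, far))
  expect_setequal(kept$gene_id[kept$event_type == "ES"], "g2")
  # window = 0 is the identity
  expect_identical(filter_positional(ev, list(near, far), window = 0), ev)
})

test_that("splice-site selection follows the event-type rules", {
  # A3SS: the longer exon's acceptor is chosen
  tA <- mk_tx("a", cbind(c(100, 300, 700), c(200, 500, 800)))
  tB <- mk_tx("b", cbind(c(100, 350, 700), c(200, 500, 800)))
  ev <- annotate_gene(new_gene("g", "chr1", "+", list(tA, tB)))
  s <- select_splice_sites(ev[ev$event_type == "A3SS", ])
  expect_equal(s$pos[s$kind == "acceptor"], 300)
  expect_equal(s$pos[s$kind == "donor"], 500)

  # IR: donor at the retained intron 5', acceptor at its 3'
  tA <- mk_tx("a", cbind(c(100, 300, 700), c(200, 600, 800)))
  tB <- mk_tx("b", cbind(c(100, 300, 500, 700), c(200, 400, 600, 800)))
  ev <- annotate_gene(new_gene("g", "chr1", "+", list(tA, tB)))
  s <- select_splice_sites(ev[ev$event_type == "IR", ])
  expect_equal(s$pos[s$kind == "donor"], 400)
  expect_equal(s$pos[s$kind == "acceptor"], 500)

  # ME: both exons contribute sites independently (4 sites)
  tA <- mk_tx("a", cbind(c(100, 300, 700), c(200, 400, 800)))
  tB <- mk_tx("b", cbind(c(100, 500, 700), c(200, 600, 800)))
  ev <- annotate_gene(new_gene("g", "chr1", "+", list(tA, tB)))
  s <- select_splice_sites(ev[ev$event_type == "ME", ])
  expect_equal(nrow(s), 4L)
  expect_equal(sort(s$pos), c(300, 400, 500, 600))
})

test_that("events and sites export to TSV and BED", {
  tA <- mk_tx("a", cbind(c(100, 300, 500, 700), c(200, 400, 600, 800)))
  tB <- mk_tx("b", cbind(c(100, 500, 700), c(200, 600, 800)))
  ev <- annotate_gene(new_gene("g", "chr1", "+", list(tA, tB)))
  tsv <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, tsv)
  back <- data.table::fread(tsv)
  expect_setequal(back$event_type, c("ES", "CNE"))
  expect_true(all(c("acceptor_pos", "donor_pos", "evidence") %in% names(back)))
  bed <- tempfile(fileext = ".bed")
  sites_to_bed(select_splice_sites(ev), bed)
  expect_equal(nrow(data.table::fread(bed, header = FALSE)), nrow(ev) * 2L)
})
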