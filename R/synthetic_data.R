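# Synthetic genomes, gene models with planted AS events, methylomes and
# read tracks with known per-feature, per-event-type effect sizes. Every
# generated truth is recorded in the returned truth tables, and all output
# is reproducible from (config, seed) alone.
#
# Gene geometry: terminal exons are long (default 2100 bp) so that internal
# event exons always survive the 2000-bp TSS/terminal positional filter;
# internal exons default to 147 bp (a typical exon length) so they exceed
# the 100-bp bins; introns default to 1000 bp so exonic and intronic bins
# never collide across sites. Strands alternate + / - across genes.

#' Simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param n_per_type Named counts of genes per AS event type
#'   (ES/ME/A3SS/A5SS/IR).
#' @param n_cne Number of constitutive-exon-only genes.
#' @param n_near_tss Number of extra ES genes planted with short terminal
#'   exons so their event exon falls within the TSS window (used to
#'   exercise the positional filter; default 0).
#' @param exon_length Internal exon length in bp (default 147).
#' @param intron_length Intron length in bp (default 1000).
#' @param terminal_exon_length Terminal exon length in bp (default 2100,
#'   i.e. > the 2000-bp positional filter window).
#' @param alt_offset Boundary shift of the shorter A3SS/A5SS alternative
#'   exon (default 50 bp).
#' @param retained_intron_length IR retained-intron length (default 400).
#' @param gene_gap Intergenic gap (default 500 bp).
#' @param chrom Chromosome name of the toy genome.
#' @param n_cell_lines Number of cell lines for read tracks.
#' @param read_rate Baseline read-start rate per bp (lambda; default 0.2,
#'   i.e. 20 expected read starts per 100-bp bin).
#' @param read_length Pre-extension read length (default 36).
#' @param effect_window Half-width of the window around ASE splice sites in
#'   which effects apply (default 500 bp).
#' @param effects `NULL` or data.frame `feature`, `event_type`,
#'   `multiplier` (> 0): read-rate multiplier inside the effect windows of
#'   that event type; unlisted combinations default to 1 (null).
#' @param features Extra feature names without planted effects (null
#'   features).
#' @param cpg_density Optional target CpG start density per bp; `NULL`
#'   (default) keeps the i.i.d. uniform-ACGT density of about 1/16.
#' @param meth_baseline Baseline per-site methylation probability
#'   (default 0.6).
#' @param meth_effects `NULL` or named numeric vector `event_type ->
#'   probability` replacing the baseline inside that type's effect windows.
#' @param input_rate Optional uniform read-start rate for a ChIP-input
#'   track (`NULL` = no input track).
#' @param nucleosome_rate Optional uniform rate for a nucleosome-occupancy
#'   track (`NULL` = none).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_per_type = c(ES = 10, ME = 10, A3SS = 10,
                                      A5SS = 10, IR = 10),
                       n_cne = 10, n_near_tss = 0,
                       exon_length = 147, intron_length = 1000,
                       terminal_exon_length = 2100, alt_offset = 50,
                       retained_intron_length = 400, gene_gap = 500,
                       chrom = "chrS", n_cell_lines = 2,
                       read_rate = 0.2, read_length = 36,
                       effect_window = 500, effects = NULL,
                       features = character(0), cpg_density = NULL,
                       meth_baseline = 0.6, meth_effects = NULL,
                       input_rate = NULL, nucleosome_rate = NULL) {
  stopifnot(all(names(n_per_type) %in% EVENT_TYPES),
            all(n_per_type >= 0), n_cne >= 0, n_near_tss >= 0,
            exon_length >= 1, intron_length >= 1,
            terminal_exon_length >= 1, alt_offset >= 1,
            retained_intron_length >= 1, gene_gap >= 0,
            n_cell_lines >= 1, read_rate > 0, read_length >= 1,
            effect_window >= 1, meth_baseline >= 0, meth_baseline <= 1)
  if (!is.null(effects)) {
    effects <- as.data.table(effects)
    stopifnot(all(c("feature", "event_type", "multiplier") %in% names(effects)),
              all(effects$event_type %in% EVENT_TYPES),
              all(effects$multiplier > 0))
  }
  if (!is.null(meth_effects)) {
    stopifnot(all(names(meth_effects) %in% EVENT_TYPES),
              all(meth_effects >= 0), all(meth_effects <= 1))
  }
  cfg <- list(seed = seed, n_per_type = n_per_type, n_cne = n_cne,
              n_near_tss = n_near_tss, exon_length = exon_length,
              intron_length = intron_length,
              terminal_exon_length = terminal_exon_length,
              alt_offset = alt_offset,
              retained_intron_length = retained_intron_length,
              gene_gap = gene_gap, chrom = chrom,
              n_cell_lines = n_cell_lines, read_rate = read_rate,
              read_length = read_length, effect_window = effect_window,
              effects = effects, features = features,
              cpg_density = cpg_density, meth_baseline = meth_baseline,
              meth_effects = meth_effects, input_rate = input_rate,
              nucleosome_rate = nucleosome_rate)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config seed=%s genes=%s+%d CNE, %d cell line(s)>\n",
              format(x$seed),
              paste(x$n_per_type, collapse = "/"), x$n_cne, x$n_cell_lines))
  invisible(x)
}

# Local (0-anchored) layout of one gene: transcript exon matrices and the
# planted truth splice sites.
gene_layout <- function(type, strand, cfg, near_tss = FALSE) {
  Tl <- if (near_tss) 800 else cfg$terminal_exon_length
  il <- if (near_tss) 400 else cfg$intron_length
  el <- cfg$exon_length
  al <- cfg$alt_offset
  ex <- function(s, len) c(s, s + len)
  mk <- function(...) do.call(rbind, list(...))
  acc_don <- function(e, idx = 1L) {
    data.table(site_index = idx, kind = c("acceptor", "donor"),
               pos = if (strand == "+") c(e[1L], e[2L]) else c(e[2L], e[1L]))
  }
  if (type %in% c("ES", "CNE")) {
    E0 <- ex(0, Tl); E1 <- ex(E0[2L] + il, el); E2 <- ex(E1[2L] + il, Tl)
    txs <- if (type == "ES") {
      list(t1 = mk(E0, E1, E2), t2 = mk(E0, E2))
    } else {
      list(t1 = mk(E0, E1, E2), t2 = mk(E0, E1, E2))
    }
    sites <- acc_don(E1)
  } else if (type == "ME") {
    E0 <- ex(0, Tl); Ea <- ex(E0[2L] + il, el); Eb <- ex(Ea[2L] + il, el)
    E3 <- ex(Eb[2L] + il, Tl)
    txs <- list(t1 = mk(E0, Ea, E3), t2 = mk(E0, Eb, E3))
    sites <- rbindlist(list(acc_don(Ea, 1L), acc_don(Eb, 2L)))
  } else if (type %in% c("A3SS", "A5SS")) {
    E0 <- ex(0, Tl)
    s <- E0[2L] + il
    long <- c(s, s + el + al)
    # the shared boundary is the donor side for A3SS, the acceptor side for
    # A5SS, both in transcript orientation
    share_end <- (type == "A3SS") == (strand == "+")
    short <- if (share_end) c(s + al, long[2L]) else c(s, s + el)
    E3 <- ex(long[2L] + il, Tl)
    txs <- list(t1 = mk(E0, long, E3), t2 = mk(E0, short, E3))
    sites <- acc_don(long)
  } else if (type == "IR") {
    E0 <- ex(0, Tl); A <- ex(E0[2L] + il, el)
    B <- ex(A[2L] + cfg$retained_intron_length, el)
    E3 <- ex(B[2L] + il, Tl)
    txs <- list(t1 = mk(E0, c(A[1L], B[2L]), E3), t2 = mk(E0, A, B, E3))
    sites <- data.table(
      site_index = 1L, kind = c("acceptor", "donor"),
      pos = if (strand == "+") c(B[1L], A[2L]) else c(A[2L], B[1L]))
  } else {
    stop("unknown layout type: ", type)
  }
  span <- max(vapply(txs, function(m) max(m[, 2L]), numeric(1)))
  list(txs = txs, sites = sites, span = span)
}

#' Generate the toy genome and gene models
#'
#' Builds, for each requested event type, genes whose two transcripts
#' realize exactly that event on an internal exon well clear of the
#' transcript ends, plus CNE-only genes with identical transcripts and
#' (optionally) near-TSS genes that the positional filter must remove.
#' Genes alternate strands and are laid out head to tail on one chromosome
#' whose sequence is random ACGT. Identical seeds give byte-identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return List of class `simulation`: `genes` (list of `gene`), `genome`
#'   (`DNAStringSet`), `truth` (list of data.tables `genes`, `sites`,
#'   `effects`) and `cfg`.
#' @export
generate_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  plan <- data.table(
    type = c(rep(names(cfg$n_per_type), cfg$n_per_type),
             rep("CNE", cfg$n_cne), rep("ES", cfg$n_near_tss)),
    near_tss = c(rep(FALSE, sum(cfg$n_per_type) + cfg$n_cne),
                 rep(TRUE, cfg$n_near_tss)))
  genes <- vector("list", nrow(plan))
  truth_genes <- vector("list", nrow(plan))
  truth_sites <- vector("list", nrow(plan))
  offset <- 0
  for (i in seq_len(nrow(plan))) {
    type <- plan$type[i]
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%04d_%s%s", i, type, if (plan$near_tss[i]) "_tss" else "")
    lay <- gene_layout(type, strand, cfg, near_tss = plan$near_tss[i])
    txs <- lapply(names(lay$txs), function(tn) {
      new_transcript(paste(gid, tn, sep = "."), gid, cfg$chrom, strand,
                     lay$txs[[tn]] + offset, coding = TRUE)
    })
    genes[[i]] <- new_gene(gid, cfg$chrom, strand, txs)
    truth_genes[[i]] <- data.table(gene_id = gid, event_type = type,
                                   strand = strand,
                                   filtered = plan$near_tss[i])
    st <- data.table::copy(lay$sites)
    st[, `:=`(gene_id = gid, event_type = type, pos = pos + offset,
              strand = strand, filtered = plan$near_tss[i])]
    truth_sites[[i]] <- st
    offset <- offset + lay$span + cfg$gene_gap
  }
  L <- as.integer(offset)
  letters4 <- c("A", "C", "G", "T")
  seq_chars <- sample(letters4, L, replace = TRUE)
  if (!is.null(cfg$cpg_density)) {
    # plant CG dinucleotides on an even grid to hit the target density
    cand <- seq(1L, L - 1L, by = 2L)
    plant <- cand[stats::runif(length(cand)) < 2 * cfg$cpg_density]
    seq_chars[plant] <- "C"
    seq_chars[plant + 1L] <- "G"
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- cfg$chrom
  all_features <- unique(c(cfg$features,
                           if (!is.null(cfg$effects)) cfg$effects$feature))
  effects <- data.table(expand.grid(feature = all_features,
                                    event_type = EVENT_TYPES,
                                    stringsAsFactors = FALSE))
  effects[, multiplier := 1]
  if (!is.null(cfg$effects)) {
    for (r in seq_len(nrow(cfg$effects))) {
      effects[feature == cfg$effects$feature[r] &
                event_type == cfg$effects$event_type[r],
              multiplier := cfg$effects$multiplier[r]]
    }
  }
  effects[, direction := ifelse(multiplier > 1, "higher_in_ASE",
                                ifelse(multiplier < 1, "higher_in_CNE",
                                       "null"))]
  setorder(effects, feature, event_type)
  structure(list(genes = genes, genome = genome,
                 truth = list(genes = rbindlist(truth_genes),
                              sites = rbindlist(truth_sites),
                              effects = effects),
                 cfg = cfg),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("<simulation %d gene(s), genome %s bp, seed %s>\n",
              length(x$genes), format(sum(Biostrings::width(x$genome))),
              format(x$cfg$seed)))
  invisible(x)
}

# Piecewise-constant read-start rate over [0, L): baseline lambda,
# multiplied inside the effect windows of each event type.
rate_intervals <- function(sim, feature) {
  cfg <- sim$cfg
  feat <- feature
  L <- sum(Biostrings::width(sim$genome))
  eff <- sim$truth$effects[sim$truth$effects$feature == feat, ]
  win <- list()
  for (r in seq_len(nrow(eff))) {
    if (eff$multiplier[r] == 1) next
    st <- sim$truth$sites
    st <- st[st$event_type == eff$event_type[r] & !st$filtered, ]
    if (nrow(st) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(st$pos - cfg$effect_window, 0) + 1,
      end = pmin(st$pos + cfg$effect_window, L)))
    win[[length(win) + 1L]] <- data.table(
      start = IRanges::start(ir) - 1, end = IRanges::end(ir),
      mult = eff$multiplier[r])
  }
  win <- if (length(win)) rbindlist(win) else {
    data.table(start = numeric(0), end = numeric(0), mult = numeric(0))
  }
  setorder(win, start)
  # complement at baseline rate
  gaps_start <- c(0, win$end)
  gaps_end <- c(win$start, L)
  base <- data.table(start = gaps_start, end = gaps_end, mult = 1)
  base <- base[base$end > base$start, ]
  iv <- rbindlist(list(win, base))
  setorder(iv, start)
  iv
}

#' Generate a read track with planted effects
#'
#' Read starts follow a Poisson process at rate `read_rate x multiplier`
#' per bp, where the multiplier is the feature's planted effect inside the
#' `effect_window` around splice sites of the affected event types and 1
#' elsewhere. Strands are Bernoulli(0.5); reads have the pre-extension
#' length of the config (strand-directed extension to 200 bp happens at
#' load time, mirroring raw-alignment input).
#'
#' @param sim A `simulation`.
#' @param feature Feature name present in the truth effects table.
#' @param rate Override of the baseline rate (default `cfg$read_rate`).
#' @param seed Optional seed for this track (defaults to the current RNG
#'   stream).
#' @return data.table `chrom`, `start`, `end`, `strand` (BED6-ready via
#'   [write_bed()]).
#' @export
generate_reads <- function(sim, feature, rate = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$cfg
  lambda <- rate %||% cfg$read_rate
  L <- sum(Biostrings::width(sim$genome))
  iv <- if (feature %in% sim$truth$effects$feature) {
    rate_intervals(sim, feature)
  } else {
    data.table(start = 0, end = L, mult = 1)
  }
  n <- stats::rpois(nrow(iv), (iv$end - iv$start) * lambda * iv$mult)
  starts <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    if (n[i] == 0L) return(numeric(0))
    floor(stats::runif(n[i], iv$start[i], iv$end[i]))
  }))
  starts <- pmin(starts, L - cfg$read_length)
  dt <- data.table(chrom = cfg$chrom, start = starts,
                   end = starts + cfg$read_length,
                   strand = sample(c("+", "-"), length(starts),
                                   replace = TRUE))
  setorder(dt, start)
  dt[]
}

#' Generate a methylome with planted effects
#'
#' Every CpG of the toy genome becomes one strand-combined functional site;
#' its methylated flag is Bernoulli with the baseline probability, replaced
#' by the per-event-type probability of `cfg$meth_effects` inside the
#' effect windows of that type's splice sites.
#'
#' @param sim A `simulation`.
#' @param seed Optional seed for this track.
#' @return data.table `chrom`, `pos`, `strand` (`"+"`), `methylated` (0/1),
#'   the on-disk methylation-call dialect.
#' @export
generate_methylome <- function(sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$cfg
  seqtrack <- track_sequence(sim$genome)
  pos <- seqtrack$cpg[[cfg$chrom]]
  p <- rep(cfg$meth_baseline, length(pos))
  if (!is.null(cfg$meth_effects)) {
    for (ty in names(cfg$meth_effects)) {
      st <- sim$truth$sites
      st <- st[st$event_type == ty & !st$filtered, ]
      for (i in seq_len(nrow(st))) {
        hit <- pos >= st$pos[i] - cfg$effect_window &
          pos < st$pos[i] + cfg$effect_window
        p[hit] <- cfg$meth_effects[[ty]]
      }
    }
  }
  data.table(chrom = cfg$chrom, pos = pos, strand = "+",
             methylated = stats::rbinom(length(pos), 1L, p))
}

#' Generate and write a complete fixture directory
#'
#' Runs [generate_genes()] and writes the genome FASTA, annotation GTF,
#' methylation TSV, one BED6 read track per (feature, cell line), optional
#' input and nucleosome tracks, and the truth tables. All randomness
#' derives from `cfg$seed`, so a rerun with the same config reproduces
#' every file byte for byte.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The `simulation`, invisibly, with `$paths` added.
#' @export
generate_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genes(cfg)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    methylation = file.path(dir, "methylation.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_effects = file.path(dir, "truth_effects.tsv"),
    reads = list())
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_gtf(sim$genes, paths$gtf)
  fwrite(generate_methylome(sim), paths$methylation, sep = "\t",
         col.names = FALSE)
  features <- unique(c(sim$cfg$features,
                       if (!is.null(sim$cfg$effects)) sim$cfg$effects$feature))
  lines <- paste0("cell", seq_len(cfg$n_cell_lines))
  for (f in features) {
    paths$reads[[f]] <- list()
    for (cl in lines) {
      p <- file.path(dir, sprintf("reads_%s_%s.bed", f, cl))
      write_bed(generate_reads(sim, f), p)
      paths$reads[[f]][[cl]] <- p
    }
  }
  if (!is.null(cfg$input_rate)) {
    paths$input <- list()
    for (cl in lines) {
      p <- file.path(dir, sprintf("input_%s.bed", cl))
      write_bed(generate_reads(sim, "__input__", rate = cfg$input_rate), p)
      paths$input[[cl]] <- p
    }
  }
  if (!is.null(cfg$nucleosome_rate)) {
    p <- file.path(dir, "nucleosome.bed")
    write_bed(generate_reads(sim, "__nucleosome__",
                             rate = cfg$nucleosome_rate), p)
    paths$nucleosome <- p
  }
  fwrite(sim$truth$genes, paths$truth_genes, sep = "\t")
  fwrite(sim$truth$sites, paths$truth_sites, sep = "\t")
  fwrite(sim$truth$effects, paths$truth_effects, sep = "\t")
  sim$paths <- paths
  invisible(sim)
}
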