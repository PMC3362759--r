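# Signal tracks: genome-sequence CpG, strand-combined CpG methylation, and
# strand-extended read intervals. All three expose per-region counts (or
# percentages) and per-position values through a common small interface used
# by the profiling module. Queries are pure; coordinates are 0-based
# half-open.

#' Sequence-CpG track from a genome
#'
#' Indexes the start positions of CpG dinucleotides (case-insensitive; `N`
#' never matches) on the forward strand of each chromosome. CpG is its own
#' reverse complement, so one strand suffices.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param label Feature label (default `"CG"`).
#' @return A `signal_track` of kind `sequence_cpg`.
#' @export
track_sequence <- function(genome, label = "CG") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cpg <- lapply(seq_along(genome), function(i) {
    as.numeric(Biostrings::start(
      Biostrings::matchPattern("CG", genome[[i]], fixed = TRUE))) - 1
  })
  names(cpg) <- names(genome)
  structure(list(kind = "sequence_cpg", label = label,
                 seqlen = stats::setNames(Biostrings::width(genome),
                                          names(genome)),
                 cpg = cpg),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track kind=%s label=%s>\n", x$kind, x$label))
  invisible(x)
}

check_chrom <- function(track, chrom, slot) {
  if (!chrom %in% names(track[[slot]])) {
    stop(sprintf("chromosome %s not present in %s track", chrom, track$kind))
  }
}

# Number of sorted values in [start, end) -- pos assumed sorted.
count_in_range <- function(pos, start, end) {
  findInterval(end - 0.5, pos) - findInterval(start - 0.5, pos)
}

#' Count CpG dinucleotides in a region
#'
#' Counts positions `p` in `[start, end - 1)` where the base at `p` is C and
#' at `p + 1` is G, i.e. CpGs fully inside the region.
#'
#' @param track A `sequence_cpg` track.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region; must lie within the sequence.
#' @return Integer count (vectorized over `start`/`end`).
#' @export
count_cpg <- function(track, chrom, start, end) {
  stopifnot(track$kind == "sequence_cpg")
  check_chrom(track, chrom, "cpg")
  if (any(start < 0) || any(end > track$seqlen[[chrom]]) || any(start >= end)) {
    stop("region outside sequence bounds")
  }
  pos <- track$cpg[[chrom]]
  as.integer(findInterval(end - 2 + 0.5, pos) - findInterval(start - 0.5, pos))
}

# Per-position CpG-start indicator over [start, end); positions outside the
# chromosome are FALSE.
cpg_window <- function(track, chrom, start, end) {
  pos <- track$cpg[[chrom]]
  out <- logical(end - start)
  hit <- pos[pos >= start & pos < end]
  out[hit - start + 1L] <- TRUE
  out
}

#' Read strand-combined CpG methylation calls
#'
#' Input dialect: headerless TSV with columns chrom, pos (0-based coordinate
#' of the + strand C of the CpG functional site), strand of the underlying
#' call, methylated flag (0/1). Calls from both strands of one CpG carry the
#' same site coordinate and are merged into one functional site; a site is
#' methylated if any merged call is methylated (conflicting duplicates are
#' logged). Malformed rows are skipped with a warning.
#'
#' @param path TSV path.
#' @param label Feature label (default `"mCG"`).
#' @return A `signal_track` of kind `methylation`.
#' @export
read_methylation <- function(path, label = "mCG") {
  empty <- function() {
    structure(list(kind = "methylation", label = label,
                   sites = list()), class = "signal_track")
  }
  if (!file.exists(path)) stop("cannot read methylation file: ", path)
  if (file.size(path) == 0L) return(empty())
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = c(1L, 3L)))
  if (ncol(dt) < 4L) stop("methylation TSV needs 4 columns")
  data.table::setnames(dt, 1:4, c("chrom", "pos", "strand", "methylated"))
  dt[, pos := suppressWarnings(as.numeric(pos))]
  dt[, methylated := suppressWarnings(as.numeric(methylated))]
  ok <- dt$strand %in% c("+", "-") & dt$methylated %in% c(0, 1) &
    !is.na(dt$pos) & dt$pos >= 0
  if (any(!ok)) {
    ep_warn(sprintf("skipping %d malformed methylation row(s)", sum(!ok)))
    dt <- dt[ok, ]
  }
  if (nrow(dt) == 0L) return(empty())
  merged <- dt[, .(methylated = any(methylated == 1),
                   conflict = length(unique(methylated)) > 1L),
               by = c("chrom", "pos")]
  n_conf <- sum(merged$conflict)
  if (n_conf > 0L) {
    ep_log(sprintf(
      "%d CpG site(s) with conflicting strand calls; methylated wins", n_conf))
  }
  sites <- lapply(split(merged, merged$chrom), function(m) {
    o <- order(m$pos)
    list(pos = m$pos[o], cmeth = cumsum(as.integer(m$methylated[o])))
  })
  structure(list(kind = "methylation", label = label, sites = sites),
            class = "signal_track")
}

#' Methylation track from merged sites in memory
#'
#' @param sites_dt data.table/data.frame with `chrom`, `pos` (0-based +
#'   strand site coordinate) and `methylated` (logical or 0/1), one row per
#'   strand-combined CpG functional site.
#' @param label Feature label (default `"mCG"`).
#' @return A `signal_track` of kind `methylation`.
#' @export
track_methylation <- function(sites_dt, label = "mCG") {
  sites_dt <- as.data.table(sites_dt)
  sites <- lapply(split(sites_dt, sites_dt$chrom), function(m) {
    o <- order(m$pos)
    list(pos = m$pos[o], cmeth = cumsum(as.integer(m$methylated[o])))
  })
  structure(list(kind = "methylation", label = label, sites = sites),
            class = "signal_track")
}

#' Methylation percentage of a region
#'
#' 100 x (methylated CpG sites) / (CpG sites) over `[start, end)`. A site
#' belongs to the region when its CpG dinucleotide `[pos, pos + 2)` lies
#' fully inside it, matching the CpG-count semantics (and symmetric under
#' reverse complement). Regions without CpG sites are flagged missing
#' (`NA` percentage) rather than imputed.
#'
#' @param track A `methylation` track.
#' @param chrom,start,end Region (vectorized over `start`/`end`).
#' @return List with `percentage` and `n_sites` vectors.
#' @export
methylation_percentage <- function(track, chrom, start, end) {
  stopifnot(track$kind == "methylation")
  s <- track$sites[[chrom]]
  if (is.null(s)) {
    n <- integer(length(start))
    return(list(percentage = rep(NA_real_, length(start)), n_sites = n))
  }
  lo <- findInterval(start - 0.5, s$pos)
  hi <- findInterval(end - 2 + 0.5, s$pos)
  n_sites <- hi - lo
  cm <- c(0, s$cmeth)
  n_meth <- cm[hi + 1L] - cm[lo + 1L]
  pct <- ifelse(n_sites > 0, 100 * n_meth / n_sites, NA_real_)
  list(percentage = pct, n_sites = as.integer(n_sites))
}

# Per-position site/methylated indicators over [start, end).
meth_window <- function(track, chrom, start, end) {
  w <- end - start
  is_site <- logical(w)
  meth <- logical(w)
  s <- track$sites[[chrom]]
  if (!is.null(s)) {
    sel <- s$pos >= start & s$pos < end
    if (any(sel)) {
      idx <- s$pos[sel] - start + 1L
      is_site[idx] <- TRUE
      cm <- c(0, s$cmeth)
      which_sel <- which(sel)
      meth[idx] <- (cm[which_sel + 1L] - cm[which_sel]) == 1
    }
  }
  list(is_site = is_site, methylated = meth)
}

#' Build a read track from intervals in memory
#'
#' Applies the strand-directed extension: `+` reads become
#' `[start, start + extension)`, `-` reads `[end - extension, end)`;
#' extensions running past the chromosome start are clamped at 0 (logged),
#' and clamped reads are kept so read counts are preserved. Identical reads
#' are not de-duplicated (raw read semantics).
#'
#' @param dt data.table/data.frame with `chrom`, `start`, `end`, `strand`.
#' @param extension Extension length in bp (default 200; 0 keeps the raw
#'   intervals).
#' @param label Feature label.
#' @return A `signal_track` of kind `reads`.
#' @export
prepare_reads <- function(dt, extension = 200, label = "reads") {
  dt <- as.data.table(dt)[, c("chrom", "start", "end", "strand")]
  if (extension > 0) {
    plus <- dt$strand == "+"
    dt[plus, end := start + extension]
    dt[!plus, start := end - extension]
    n_clamp <- sum(dt$start < 0)
    if (n_clamp > 0L) {
      ep_log(sprintf("clamped %d extended read(s) at chromosome start",
                     n_clamp))
      dt[start < 0, start := 0]
    }
  }
  ir <- lapply(split(dt, dt$chrom), function(d) {
    IRanges::IRanges(start = d$start + 1L, end = d$end)
  })
  structure(list(kind = "reads", label = label, reads = dt, ir = ir,
                 cov_cache = new.env(parent = emptyenv())),
            class = "signal_track")
}

#' Load a BED6 read track
#'
#' Reads alignments from a BED6 file and extends them in the direction of
#' their strand (see [prepare_reads()]). Records without a `+`/`-` strand
#' are skipped with a warning.
#'
#' @param path BED6 path.
#' @param extension Extension length in bp (default 200).
#' @param label Feature label (defaults to the file name).
#' @return A `signal_track` of kind `reads`.
#' @export
load_reads <- function(path, extension = 200,
                       label = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  if (file.size(path) == 0L) {
    return(prepare_reads(data.table(chrom = character(0), start = numeric(0),
                                    end = numeric(0), strand = character(0)),
                         extension = extension, label = label))
  }
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("BED6 input needs 6 columns: ", path)
  dt <- dt[, c(1L, 2L, 3L, 6L)]
  data.table::setnames(dt, c("chrom", "start", "end", "strand"))
  dt[, chrom := as.character(chrom)]
  ok <- dt$strand %in% c("+", "-")
  if (any(!ok)) {
    ep_warn(sprintf("skipping %d read(s) without +/- strand", sum(!ok)))
    dt <- dt[ok, ]
  }
  prepare_reads(dt, extension = extension, label = label)
}

#' Count reads overlapping a region
#'
#' A read counts when its (extended) interval intersects `[start, end)` by
#' at least 1 bp.
#'
#' @param track A `reads` track.
#' @param chrom,start,end Region (vectorized over `start`/`end`).
#' @return Integer vector of counts.
#' @export
region_read_count <- function(track, chrom, start, end) {
  stopifnot(track$kind == "reads")
  ir <- track$ir[[chrom]]
  if (is.null(ir)) return(integer(length(start)))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  IRanges::countOverlaps(q, ir)
}

chrom_coverage <- function(track, chrom) {
  cov <- get0(chrom, envir = track$cov_cache)
  if (is.null(cov)) {
    ir <- track$ir[[chrom]]
    cov <- if (is.null(ir)) S4Vectors::Rle(integer(0)) else IRanges::coverage(ir)
    assign(chrom, cov, envir = track$cov_cache)
  }
  cov
}

#' Per-position read coverage over a window
#'
#' `coverage[i]` is the number of (extended) reads overlapping position
#' `start + i - 1`.
#'
#' @param track A `reads` track.
#' @param chrom,start,end Window, 0-based half-open.
#' @return Integer vector of length `end - start`.
#' @export
position_coverage <- function(track, chrom, start, end) {
  stopifnot(track$kind == "reads")
  cov <- chrom_coverage(track, chrom)
  w <- as.integer(end - start)
  out <- integer(w)
  lo <- max(start + 1, 1)          # 1-based within the Rle
  hi <- min(end, length(cov))
  if (hi >= lo) {
    vals <- as.integer(S4Vectors::window(cov, lo, hi))
    out[(lo - start):(hi - start)] <- vals
  }
  out
}

#' Write read intervals as BED6
#'
#' @param dt data.table with `chrom`, `start`, `end`, `strand` (and
#'   optionally `name`, `score`).
#' @param path Output path.
#' @export
write_bed <- function(dt, path) {
  bed <- data.table(chrom = dt$chrom, start = as.integer(dt$start),
                    end = as.integer(dt$end),
                    name = if ("name" %in% names(dt)) dt$name else ".",
                    score = if ("score" %in% names(dt)) dt$score else 0L,
                    strand = dt$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
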