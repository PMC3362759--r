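# Splice-site bins and position metaprofiles.
#
# Each splice site contributes an exonic and an intronic bin of bin_length
# bp (default 100) anchored at the site boundary; an event's acceptor+donor
# pair therefore yields 4 bins. Metaprofiles cover -500..+200 around
# acceptors and -200..+500 around donors in transcript orientation, with
# negative offsets on the intronic side of the acceptor and the exonic side
# of the donor (the x-axis convention of the profile plots).

BIN_LEVELS <- c("acceptor_intronic", "acceptor_exonic",
                "donor_exonic", "donor_intronic")

#' Exonic and intronic bins of splice sites
#'
#' For a `+` strand acceptor at `a`: intronic `[a - L, a)`, exonic
#' `[a, a + L)`; for a `+` strand donor at `d`: exonic `[d - L, d)`,
#' intronic `[d, d + L)`. Minus-strand sites mirror. Exons shorter than
#' `2 * bin_length` can make a site pair's exonic bins overlap; both bins
#' are kept since sites are treated independently.
#'
#' @param sites Sites table from [select_splice_sites()].
#' @param bin_length Bin size in bp (default 100).
#' @return data.table with one row per (site, side): site columns plus
#'   `side`, `bin` (e.g. `"acceptor_exonic"`), `start`, `end`.
#' @export
make_bins <- function(sites, bin_length = 100) {
  stopifnot_scalar_count(bin_length, "bin_length")
  two <- rbindlist(list(sites, sites))
  two[, side_left := rep(c(TRUE, FALSE), each = nrow(sites))]
  two[, start := ifelse(side_left, pos - bin_length, pos)]
  two[, end := start + bin_length]
  # which side of the boundary is exonic: downstream of an acceptor,
  # upstream of a donor, in transcript orientation
  exon_on_right <- (two$kind == "acceptor") == (two$strand == "+")
  two[, side := ifelse(side_left != exon_on_right, "exonic", "intronic")]
  two[, bin := paste(kind, side, sep = "_")]
  two[, side_left := NULL]
  setorder(two, site_id, bin)
  two[]
}

#' Collect per-bin signal levels
#'
#' Maps every track to every bin: CpG counts for `sequence_cpg` tracks,
#' methylation percentages for `methylation` tracks (bins without CpG sites
#' are flagged missing), and overlapping-read counts for `reads` tracks.
#' Each (splice site, bin, feature, cell line) combination is one
#' independent observation; observations from all cell lines are pooled
#' downstream.
#'
#' @param sites Sites table from [select_splice_sites()].
#' @param tracks Named list: `feature -> named list(cell_line -> track)`.
#' @param bin_length Bin size in bp (default 100).
#' @return Long data.table of observations: site/event columns plus `bin`,
#'   `feature`, `cell_line`, `value`, `missing`.
#' @export
collect_levels <- function(sites, tracks, bin_length = 100) {
  stopifnot(length(tracks) >= 1L)
  bins <- make_bins(sites, bin_length = bin_length)
  out <- list()
  for (feature in names(tracks)) {
    lines <- tracks[[feature]]
    if (length(lines) == 0L) {
      stop(sprintf("feature %s has no tracks in any cell line", feature))
    }
    for (cl in names(lines)) {
      track <- lines[[cl]]
      obs <- bins[, c("site_id", "event_id", "event_type", "chrom", "strand",
                      "kind", "bin", "start", "end", "exon_ordinal")]
      vals <- numeric(nrow(obs))
      miss <- logical(nrow(obs))
      for (chr in unique(obs$chrom)) {
        i <- which(obs$chrom == chr)
        vals[i] <- switch(
          track$kind,
          sequence_cpg = count_cpg(track, chr, obs$start[i], obs$end[i]),
          reads = region_read_count(track, chr, obs$start[i], obs$end[i]),
          methylation = {
            mp <- methylation_percentage(track, chr, obs$start[i], obs$end[i])
            miss[i] <- mp$n_sites == 0L
            mp$percentage
          },
          stop("unknown track kind: ", track$kind))
      }
      obs[, `:=`(feature = feature, cell_line = cl, value = vals,
                 missing = miss)]
      out[[length(out) + 1L]] <- obs
    }
  }
  res <- rbindlist(out)
  setorder(res, feature, cell_line, site_id, bin)
  res[]
}

profile_offsets <- function(site_kind) {
  if (site_kind == "acceptor") -500:200 else -200:500
}

# Genomic base index covered by offset o at a site: pos + o on "+",
# pos - 1 - o on "-" (windows flip with the transcript).
offset_window <- function(pos, strand, offsets) {
  if (strand == "+") {
    c(start = pos + min(offsets), end = pos + max(offsets) + 1)
  } else {
    c(start = pos - 1 - max(offsets), end = pos - min(offsets))
  }
}

#' Position metaprofile around splice sites
#'
#' For each offset of the site-kind window, averages the per-position value
#' across all supplied sites of that kind (minus-strand windows are
#' reversed so offsets stay in transcript orientation). Per-position values
#' are: read coverage for `reads` tracks; CpG percentage (100 x fraction of
#' sites with a CpG starting there) for `sequence_cpg`; methylation
#' percentage (100 x methylated / CpG sites at that position, `NaN` where no
#' site has a CpG) for `methylation`.
#'
#' @param sites Sites table; only rows with `kind == site_kind` are used.
#' @param track A `signal_track`.
#' @param site_kind `"acceptor"` or `"donor"`.
#' @param offsets Integer offsets (default -500..200 for acceptors,
#'   -200..500 for donors).
#' @return data.table: `offset`, `value`, `n_sites`, `site_kind`, `feature`.
#' @export
position_profile <- function(sites, track, site_kind,
                             offsets = profile_offsets(site_kind)) {
  site_kind <- match.arg(site_kind, c("acceptor", "donor"))
  ss <- sites[sites$kind == site_kind, ]
  if (nrow(ss) == 0L) stop("no sites of kind ", site_kind)
  w <- length(offsets)
  num <- numeric(w)
  den <- numeric(w)
  for (i in seq_len(nrow(ss))) {
    win <- offset_window(ss$pos[i], ss$strand[i], offsets)
    vals <- switch(
      track$kind,
      reads = {
        den <- den + 1
        position_coverage(track, ss$chrom[i], win["start"], win["end"])
      },
      sequence_cpg = {
        den <- den + 1
        100 * cpg_window(track, ss$chrom[i], win["start"], win["end"])
      },
      methylation = {
        mw <- meth_window(track, ss$chrom[i], win["start"], win["end"])
        if (ss$strand[i] == "-") {
          mw <- lapply(mw, rev)
        }
        den <- den + mw$is_site
        num <- num + 100 * mw$methylated
        NULL
      },
      stop("unknown track kind: ", track$kind))
    if (!is.null(vals)) {
      if (ss$strand[i] == "-") vals <- rev(vals)
      num <- num + vals
    }
  }
  value <- ifelse(den > 0, num / den, NaN)
  data.table(offset = offsets, value = value, n_sites = nrow(ss),
             site_kind = site_kind, feature = track$label)
}

#' Metaprofile averaged across cell lines
#'
#' Computes [position_profile()] per cell line and returns the unweighted
#' mean profile.
#'
#' @param sites Sites table.
#' @param tracks_by_line Named list `cell_line -> track` for one feature.
#' @param site_kind,offsets As in [position_profile()].
#' @export
position_profile_multi <- function(sites, tracks_by_line, site_kind,
                                   offsets = profile_offsets(site_kind)) {
  profs <- lapply(tracks_by_line, function(track) {
    position_profile(sites, track, site_kind, offsets)$value
  })
  base <- position_profile(sites, tracks_by_line[[1L]], site_kind, offsets)
  base$value <- Reduce(`+`, profs) / length(profs)
  base
}

#' Sliding-window smoothing of a profile
#'
#' Centered moving average of width `window` bp (147 by default, the
#' typical exon length); at the edges the window truncates to the available
#' positions. Intended for CpG and methylation profiles; read profiles are
#' left unsmoothed because reads are already extended to 200 bp.
#'
#' @param profile data.table from [position_profile()] (or any table with a
#'   `value` column), or a plain numeric vector.
#' @param window Odd window width in bp (default 147).
#' @param na.rm Drop `NaN`/`NA` positions from each window's mean.
#' @return Same shape as the input with smoothed values.
#' @export
smooth_profile <- function(profile, window = 147, na.rm = FALSE) {
  if (window < 1) stop("window must be >= 1")
  if (window %% 2 == 0) stop("window must be odd (centered)")
  vec_in <- is.numeric(profile)
  x <- if (vec_in) profile else profile$value
  h <- (window - 1) / 2
  n <- length(x)
  miss <- !is.finite(x)
  xz <- ifelse(miss, 0, x)
  cs <- c(0, cumsum(xz))
  cn <- c(0, cumsum(!miss))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi + 1L] - cs[lo]
  if (na.rm) {
    counts <- cn[hi + 1L] - cn[lo]
    out <- ifelse(counts > 0, sums / counts, NaN)
  } else {
    any_miss <- (cn[hi + 1L] - cn[lo]) < (hi - lo + 1L)
    out <- ifelse(any_miss, NaN, sums / (hi - lo + 1L))
  }
  if (vec_in) return(out)
  res <- data.table::copy(profile)
  res$value <- out
  res
}

#' Stratify events by exon ordinal
#'
#' Partitions events by the ordinal of the event exon in its evidence
#' transcript (e.g. restrict to 2nd-4th exons to control for positional
#' effects along the gene body); downstream statistics can then be run per
#' stratum. Empty strata are dropped with a log message.
#'
#' @param events Events data.table.
#' @param ordinals Integer set of ordinals to keep.
#' @return Named list of events data.tables, one per ordinal.
#' @export
stratify_by_ordinal <- function(events, ordinals) {
  out <- list()
  for (o in sort(unique(as.integer(ordinals)))) {
    sub <- events[!is.na(events$exon_ordinal) & events$exon_ordinal == o, ]
    if (nrow(sub) == 0L) {
      ep_log(sprintf("ordinal %d: no events; stratum skipped", o))
      next
    }
    out[[as.character(o)]] <- sub
  }
  out
}

#' Write a long observation table or profile to TSV
#'
#' @param x data.table.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}
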