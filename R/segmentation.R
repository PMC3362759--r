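# Gene segmentation and binary/decimal transcript coding.
#
# The union of all exon boundaries of a gene's transcripts partitions the
# gene span into segments; each transcript is then a bit-vector over those
# segments (1 = segment exonic in that transcript). The decimal code is the
# base-2 value of the bit pattern with the most-significant bit at the
# transcript's 5' end. Event recognition itself is done with geometric
# predicates on exon coordinates (see classify_pairwise); the coding is a
# compact bookkeeping representation of the same information.

#' Segment a gene by the union of its transcripts' exon boundaries
#'
#' @param g A `gene`.
#' @return List of class `segmentation`: `boundaries` (sorted unique
#'   coordinates), `segments` (data.table `start`,`end` tiling the gene span
#'   without gaps or overlaps), `inclusion` (transcripts x segments 0/1
#'   matrix, rows named by transcript_id) and `strand`.
#' @export
segment_gene <- function(g) {
  bnd <- sort(unique(unlist(lapply(g$transcripts, function(t) {
    c(t$exons[, "start"], t$exons[, "end"])
  }))))
  segs <- data.table(start = bnd[-length(bnd)], end = bnd[-1L])
  inc <- matrix(0L, nrow = length(g$transcripts), ncol = nrow(segs),
                dimnames = list(names(g$transcripts), NULL))
  for (i in seq_along(g$transcripts)) {
    ex <- g$transcripts[[i]]$exons
    for (j in seq_len(nrow(ex))) {
      inc[i, segs$start >= ex[j, "start"] & segs$end <= ex[j, "end"]] <- 1L
    }
  }
  structure(list(boundaries = bnd, segments = segs, inclusion = inc,
                 strand = g$strand),
            class = "segmentation")
}

#' Decimal code of a bit-vector
#'
#' Standard base-2 interpretation; the caller supplies bits with the
#' most-significant bit first (i.e. 5'-most segment in transcript
#' orientation).
#'
#' @param bits Vector of 0/1.
#' @return Numeric scalar.
#' @export
encode_decimal <- function(bits) {
  if (length(bits) == 0L) stop("empty bit-vector")
  if (!all(bits %in% c(0, 1))) stop("bits must be 0 or 1")
  sum(as.numeric(bits) * 2^(rev(seq_along(bits)) - 1))
}

#' Decimal code of one transcript over a segmentation
#'
#' Bits are ordered 5' to 3' in transcript orientation (reversed on the
#' minus strand) before base-2 conversion.
#'
#' @param seg A `segmentation`.
#' @param transcript_id Row to encode.
#' @return Numeric scalar.
#' @export
transcript_decimal <- function(seg, transcript_id) {
  bits <- seg$inclusion[transcript_id, ]
  if (seg$strand == "-") bits <- rev(bits)
  encode_decimal(bits)
}

#' Reconstruct a transcript's exons from its inclusion bits
#'
#' Merges runs of consecutive included segments back into exons; exact
#' recovery of the original exon set is a structural invariant of
#' [segment_gene()].
#'
#' @param seg A `segmentation`.
#' @param transcript_id Row to reconstruct.
#' @return Matrix of `start`, `end` rows.
#' @export
reconstruct_exons <- function(seg, transcript_id) {
  bits <- seg$inclusion[transcript_id, ]
  out <- NULL
  i <- 1L
  while (i <= length(bits)) {
    if (bits[i] == 1L) {
      j <- i
      while (j < length(bits) && bits[j + 1L] == 1L) j <- j + 1L
      out <- rbind(out, c(seg$segments$start[i], seg$segments$end[j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2L)
  colnames(out) <- c("start", "end")
  out
}
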