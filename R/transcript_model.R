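# Transcript and gene models parsed from GTF.
#
# All coordinates inside the package are 0-based, half-open [start, end):
# GTF I/O converts from/to the 1-based inclusive convention at the boundary.
# Splice-site and junction positions are boundary coordinates in the same
# 0-based system (the number of bases to the left of the boundary).

#' Construct a transcript
#'
#' A transcript is an ordered set of non-overlapping exons on one strand of
#' one chromosome. Exons are stored in genomic order; transcript orientation
#' (5' to 3') follows the strand.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of 0-based half-open
#'   `start`, `end` coordinates; rows may be unsorted.
#' @param coding Logical flag; event annotation is restricted to coding
#'   transcripts upstream of this constructor.
#' @return An object of class `transcript`.
#' @export
new_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           coding = TRUE) {
  exons <- as.matrix(exons)
  if (ncol(exons) < 2L) stop("exons must have start and end columns")
  exons <- exons[, 1:2, drop = FALSE]
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  t <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = match.arg(strand, c("+", "-")),
         exons = exons,
         coding = isTRUE(coding)),
    class = "transcript")
  err <- validate_transcript(t)
  if (!isTRUE(err)) stop(err)
  t
}

#' Validate a transcript's exon structure
#'
#' @param t A `transcript`.
#' @return `TRUE` if valid, otherwise a character description of the first
#'   violated invariant.
#' @export
validate_transcript <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 1L) return("transcript has no exons")
  if (any(ex[, "start"] >= ex[, "end"])) return("exon with start >= end")
  if (nrow(ex) > 1L) {
    gaps <- ex[-1L, "start"] - ex[-nrow(ex), "end"]
    if (any(gaps < 1)) return("overlapping or abutting exons (intron length < 1)")
  }
  TRUE
}

n_exons <- function(t) nrow(t$exons)

# Genomic span of the transcript as c(start, end).
transcript_span <- function(t) c(t$exons[1L, "start"], t$exons[nrow(t$exons), "end"])

#' Construct a gene
#'
#' @param gene_id Identifier shared by all member transcripts.
#' @param chrom,strand Location; all transcripts must agree.
#' @param transcripts List of `transcript` objects.
#' @return An object of class `gene`.
#' @export
new_gene <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  for (t in transcripts) {
    if (!identical(t$gene_id, gene_id) || !identical(t$strand, strand) ||
        !identical(t$chrom, chrom)) {
      stop("all transcripts of a gene must share gene_id, chrom and strand")
    }
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s)>\n", x$transcript_id,
              x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

#' @export
print.gene <- function(x, ...) {
  cat(sprintf("<gene %s %s:%s %d transcript(s)>\n", x$gene_id, x$chrom,
              x$strand, length(x$transcripts)))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses exon features, groups them into transcripts and genes (grouping is
#' by the `gene_id` attribute, matching Ensembl annotation semantics), and
#' converts 1-based inclusive GTF coordinates to the package's 0-based
#' half-open convention. A transcript is treated as coding when a
#' `transcript_biotype`/`gene_biotype` attribute says `protein_coding`, or,
#' failing that, when the file contains CDS features for it; files carrying
#' neither kind of evidence are assumed fully coding (logged).
#' Transcripts violating structural invariants (empty, start >= end,
#' overlapping exons) are skipped with a warning rather than aborting the
#' parse.
#'
#' @param path GTF file path.
#' @param coding_only Drop non-coding transcripts (default `TRUE`).
#' @return List of `gene` objects.
#' @export
read_gtf <- function(path, coding_only = TRUE) {
  if (!file.exists(path)) stop("cannot read GTF file: ", path)
  if (file.size(path) == 0L) return(list())
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(list())
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(list())
  biotype <- ex[["transcript_biotype"]] %||% ex[["gene_biotype"]]
  cds_tx <- unique(df$transcript_id[df$type == "CDS"])
  if (!is.null(biotype)) {
    coding <- !is.na(biotype) & biotype == "protein_coding"
  } else if (length(cds_tx)) {
    coding <- ex$transcript_id %in% cds_tx
  } else {
    ep_log("GTF has no biotype attributes or CDS features; ",
           "assuming all transcripts are coding")
    coding <- rep(TRUE, nrow(ex))
  }
  ex_dt <- data.table(
    chrom = as.character(ex$seqnames),
    start = as.numeric(ex$start) - 1,  # to 0-based half-open
    end = as.numeric(ex$end),
    strand = as.character(ex$strand),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    coding = coding)
  genes <- list()
  for (gid in unique(ex_dt$gene_id)) {
    gdt <- ex_dt[ex_dt$gene_id == gid, ]
    txs <- list()
    for (tid in unique(gdt$transcript_id)) {
      tdt <- gdt[gdt$transcript_id == tid, ]
      is_coding <- all(tdt$coding)
      if (coding_only && !is_coding) next
      if (any(tdt$start >= tdt$end)) {
        ep_warn(sprintf("skipping transcript %s: exon with start >= end", tid))
        next
      }
      t <- tryCatch(
        new_transcript(tid, gid, tdt$chrom[1L], tdt$strand[1L],
                       cbind(tdt$start, tdt$end), coding = is_coding),
        error = function(e) {
          ep_warn(sprintf("skipping transcript %s: %s", tid, conditionMessage(e)))
          NULL
        })
      if (!is.null(t)) txs[[tid]] <- t
    }
    if (length(txs)) {
      genes[[gid]] <- new_gene(gid, txs[[1L]]$chrom, txs[[1L]]$strand, txs)
    }
  }
  unname(genes)
}

#' Write gene models to a GTF file
#'
#' Emits one exon feature per exon, converting back to 1-based inclusive
#' coordinates; coding status is recorded as a `transcript_biotype`
#' attribute. Output is deterministic: genes, transcripts and exons are
#' written in their stored order.
#'
#' @param genes List of `gene` objects.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    for (t in g$transcripts) {
      bt <- if (t$coding) "protein_coding" else "processed_transcript"
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
        g$gene_id, t$transcript_id, bt)
      lines <- c(lines, sprintf(
        "%s\tepisplice\texon\t%d\t%d\t.\t%s\t.\t%s",
        t$chrom, as.integer(t$exons[, "start"]) + 1L,
        as.integer(t$exons[, "end"]), t$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Internal exons of a transcript
#'
#' Excludes the first and last exon in transcript orientation (which are the
#' genomically first and last regardless of strand); transcripts with two or
#' fewer exons have no internal exons.
#'
#' @param t A `transcript`.
#' @return Matrix of `start`, `end` rows (possibly zero rows).
#' @export
internal_exons <- function(t) {
  n <- nrow(t$exons)
  if (n <= 2L) return(t$exons[0L, , drop = FALSE])
  t$exons[2:(n - 1L), , drop = FALSE]
}

#' Exon-intron junctions of a transcript
#'
#' One junction per intron. The donor is the intron 5' boundary and the
#' acceptor the intron 3' boundary in transcript orientation, so the two
#' swap genomic sides on the minus strand.
#'
#' @param t A `transcript`.
#' @return data.table with `donor_pos`, `acceptor_pos`, `strand` (zero rows
#'   for single-exon transcripts).
#' @export
junctions <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) {
    return(data.table(donor_pos = numeric(0), acceptor_pos = numeric(0),
                      strand = character(0)))
  }
  left <- t$exons[-n, "end"]     # genomic intron starts (boundaries)
  right <- t$exons[-1L, "start"] # genomic intron ends
  if (t$strand == "+") {
    data.table(donor_pos = left, acceptor_pos = right, strand = "+")
  } else {
    data.table(donor_pos = right, acceptor_pos = left, strand = "-")
  }
}

#' Export exons as BED6
#'
#' @param genes List of `gene` objects.
#' @param path Output path.
#' @export
exons_to_bed <- function(genes, path) {
  rows <- rbindlist(lapply(genes, function(g) {
    rbindlist(lapply(g$transcripts, function(t) {
      data.table(chrom = t$chrom, start = as.integer(t$exons[, "start"]),
                 end = as.integer(t$exons[, "end"]),
                 name = t$transcript_id, score = 0L, strand = t$strand)
    }))
  }))
  fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
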