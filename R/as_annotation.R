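# Classification of alternative-splicing events and constitutive exons.
#
# Events are recognized by geometric predicates on the exon coordinates of
# transcript pairs within a gene, applied to internal exons only:
#
#   ES    exon skipping: an internal exon of one transcript is absent from
#         the other, which splices directly between the two flanking
#         junctions (single-exon skipping only).
#   ME    mutually exclusive exons: two non-overlapping internal exons, one
#         per transcript, between a shared upstream donor and shared
#         downstream acceptor.
#   A3SS  alternative acceptor: overlapping internal exons sharing the
#         donor-side boundary but differing at the acceptor side, both
#         spliced from a shared upstream donor junction.
#   A5SS  alternative donor: overlapping internal exons sharing the
#         acceptor-side boundary but differing at the donor side, both
#         spliced to a shared downstream acceptor junction.
#   IR    intron retention: an internal exon of one transcript spans exactly
#         two consecutive exons of the other; the intron between them is
#         retained.
#   CNE   constitutive internal exon: identical boundaries in every
#         transcript whose span contains it, internal in each, and not
#         participating in any detected event.
#
# Acceptor/donor are labelled in transcript orientation, so genomic roles
# flip on the minus strand. Cassette-exon superclasses, multi-exon skipping
# and alternative first/last exons are out of scope.

EVENT_TYPES <- c("ES", "ME", "A3SS", "A5SS", "IR")
ALL_EVENT_TYPES <- c(EVENT_TYPES, "CNE")

empty_events <- function() {
  data.table(event_type = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             exon_start = numeric(0), exon_end = numeric(0),
             exon2_start = numeric(0), exon2_end = numeric(0),
             intron_start = numeric(0), intron_end = numeric(0),
             tx_a = character(0), tx_b = character(0),
             exon_ordinal = integer(0), site_key = character(0))
}

# Ordinal (1-based, transcript orientation) of exon (s,e) in transcript t;
# NA_integer_ if absent.
exon_ordinal_in <- function(t, s, e) {
  k <- which(t$exons[, "start"] == s & t$exons[, "end"] == e)
  if (length(k) != 1L) return(NA_integer_)
  if (t$strand == "+") as.integer(k) else as.integer(nrow(t$exons) - k + 1L)
}

has_exon <- function(t, s, e) {
  any(t$exons[, "start"] == s & t$exons[, "end"] == e)
}

any_exon_overlap <- function(t, s, e) {
  any(overlaps(t$exons[, "start"], t$exons[, "end"], s, e))
}

# De-duplication key: event type + sorted unique boundary coordinates of the
# defining splice sites.
make_site_key <- function(event_type, chrom, coords) {
  paste(event_type, chrom, paste(sort(unique(coords)), collapse = ","),
        sep = ":")
}

event_row <- function(event_type, gene_id, chrom, strand,
                      exon, exon2 = c(NA_real_, NA_real_),
                      intron = c(NA_real_, NA_real_),
                      tx_a, tx_b, exon_ordinal, key_coords) {
  data.table(event_type = event_type, gene_id = gene_id, chrom = chrom,
             strand = strand,
             exon_start = exon[1L], exon_end = exon[2L],
             exon2_start = exon2[1L], exon2_end = exon2[2L],
             intron_start = intron[1L], intron_end = intron[2L],
             tx_a = tx_a, tx_b = tx_b,
             exon_ordinal = as.integer(exon_ordinal),
             site_key = make_site_key(event_type, chrom, key_coords))
}

# One-directional scan: internal exons of tA against the structure of tB.
classify_directional <- function(tA, tB) {
  out <- list()
  nA <- nrow(tA$exons)
  if (nA < 3L) return(out)
  strand <- tA$strand
  chrom <- tA$chrom
  gid <- tA$gene_id
  exB <- tB$exons
  nB <- nrow(exB)
  intronsB <- if (nB >= 2L) {
    cbind(start = exB[-nB, "end"], end = exB[-1L, "start"])
  } else {
    matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  for (k in 2:(nA - 1L)) {
    s <- tA$exons[k, "start"]; e <- tA$exons[k, "end"]
    p_end <- tA$exons[k - 1L, "end"]    # upstream-flank junction (genomic)
    n_start <- tA$exons[k + 1L, "start"]
    ordinal <- exon_ordinal_in(tA, s, e)

    # ES: tB splices p_end -> n_start directly and nothing of tB touches E
    if (nrow(intronsB) &&
        any(intronsB[, "start"] == p_end & intronsB[, "end"] == n_start) &&
        !any_exon_overlap(tB, s, e)) {
      out[[length(out) + 1L]] <- event_row(
        "ES", gid, chrom, strand, c(s, e),
        tx_a = tA$transcript_id, tx_b = tB$transcript_id,
        exon_ordinal = ordinal, key_coords = c(s, e))
    }

    # ME: against each internal exon of tB
    if (nB >= 3L) {
      for (l in 2:(nB - 1L)) {
        s2 <- exB[l, "start"]; e2 <- exB[l, "end"]
        if (overlaps(s, e, s2, e2)) {
          # A3SS/A5SS: overlapping internal exons differing at one boundary,
          # with the introns flanking the differing boundary spliced from a
          # shared far junction (a true splice-site choice; this also keeps
          # IR partner exons from masquerading as A3SS/A5SS)
          p2_end <- exB[l - 1L, "end"]
          n2_start <- exB[l + 1L, "start"]
          if (e == e2 && s != s2 && p_end == p2_end) {
            type <- if (strand == "+") "A3SS" else "A5SS"
          } else if (s == s2 && e != e2 && n_start == n2_start) {
            type <- if (strand == "+") "A5SS" else "A3SS"
          } else {
            type <- NA_character_
          }
          if (!is.na(type)) {
            first_is_A <- (s < s2) || (s == s2 && e < e2)
            exon1 <- if (first_is_A) c(s, e) else c(s2, e2)
            exon2 <- if (first_is_A) c(s2, e2) else c(s, e)
            own <- if (first_is_A) tA else tB
            out[[length(out) + 1L]] <- event_row(
              type, gid, chrom, strand, exon1, exon2 = exon2,
              tx_a = tA$transcript_id, tx_b = tB$transcript_id,
              exon_ordinal = exon_ordinal_in(own, exon1[1L], exon1[2L]),
              key_coords = c(s, e, s2, e2))
          }
        } else if (exB[l - 1L, "end"] == p_end &&
                   exB[l + 1L, "start"] == n_start &&
                   !has_exon(tB, s, e) && !has_exon(tA, s2, e2)) {
          first_is_A <- s < s2
          exon1 <- if (first_is_A) c(s, e) else c(s2, e2)
          exon2 <- if (first_is_A) c(s2, e2) else c(s, e)
          own <- if (first_is_A) tA else tB
          out[[length(out) + 1L]] <- event_row(
            "ME", gid, chrom, strand, exon1, exon2 = exon2,
            tx_a = tA$transcript_id, tx_b = tB$transcript_id,
            exon_ordinal = exon_ordinal_in(own, exon1[1L], exon1[2L]),
            key_coords = c(s, e, s2, e2))
        }
      }
    }

    # IR: E spans exactly two consecutive exons of tB
    if (nB >= 2L) {
      for (m in 1:(nB - 1L)) {
        if (exB[m, "start"] == s && exB[m + 1L, "end"] == e) {
          out[[length(out) + 1L]] <- event_row(
            "IR", gid, chrom, strand, c(s, e),
            intron = c(exB[m, "end"], exB[m + 1L, "start"]),
            tx_a = tA$transcript_id, tx_b = tB$transcript_id,
            exon_ordinal = ordinal,
            key_coords = c(exB[m, "end"], exB[m + 1L, "start"]))
        }
      }
    }
  }
  out
}

#' Classify AS events between two transcripts
#'
#' Applies the geometric event predicates to the internal exons of each
#' transcript against the other, in both directions, and de-duplicates by
#' event type and splice-site tuple.
#'
#' @param tA,tB `transcript` objects from the same gene and strand.
#' @return Events data.table (one row per event; `exon2_*` holds the second
#'   exon for ME and the partner exon for A3SS/A5SS, `intron_*` the retained
#'   intron for IR).
#' @export
classify_pairwise <- function(tA, tB) {
  stopifnot(identical(tA$gene_id, tB$gene_id),
            identical(tA$strand, tB$strand))
  rows <- c(classify_directional(tA, tB), classify_directional(tB, tA))
  if (!length(rows)) return(empty_events())
  ev <- rbindlist(rows)
  setorder(ev, site_key, tx_a, tx_b)
  ev[!duplicated(ev$site_key), ]
}

# Constitutive internal exons of a gene, excluding exons participating in
# any of the supplied events.
find_cne <- function(g, events) {
  participating <- character(0)
  if (nrow(events)) {
    pc <- function(s, e) paste(s, e, sep = "-")
    participating <- c(
      pc(events$exon_start, events$exon_end),
      pc(events$exon2_start, events$exon2_end),
      # IR: the two partner exons flanking the retained intron
      pc(events$exon_start[events$event_type == "IR"],
         events$intron_start[events$event_type == "IR"]),
      pc(events$intron_end[events$event_type == "IR"],
         events$exon_end[events$event_type == "IR"]))
  }
  spans <- lapply(g$transcripts, transcript_span)
  cand <- unique(rbindlist(lapply(g$transcripts, function(t) {
    ie <- internal_exons(t)
    data.table(start = ie[, "start"], end = ie[, "end"])
  })))
  out <- list()
  if (nrow(cand) == 0L) return(out)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (paste(s, e, sep = "-") %in% participating) next
    ok <- TRUE
    owner <- NULL
    for (t in g$transcripts) {
      sp <- transcript_span(t)
      if (sp[1L] <= s && sp[2L] >= e) {
        ie <- internal_exons(t)
        if (!any(ie[, "start"] == s & ie[, "end"] == e)) { ok <- FALSE; break }
        if (is.null(owner)) owner <- t
      }
    }
    if (ok && !is.null(owner)) {
      out[[length(out) + 1L]] <- event_row(
        "CNE", g$gene_id, g$chrom, g$strand, c(s, e),
        tx_a = owner$transcript_id, tx_b = owner$transcript_id,
        exon_ordinal = exon_ordinal_in(owner, s, e), key_coords = c(s, e))
    }
  }
  out
}

#' Annotate AS events and constitutive exons of a gene
#'
#' Runs [classify_pairwise()] over all unordered transcript pairs,
#' de-duplicates events by (type, splice-site tuple), then adds CNE exons:
#' internal exons with identical boundaries in every transcript of the gene
#' whose genomic span contains them and that participate in no detected
#' event. Output ordering is canonical (independent of transcript input
#' order) and event ids are assigned per gene.
#'
#' @param g A `gene`.
#' @return Events data.table with `event_id`.
#' @export
annotate_gene <- function(g) {
  txs <- g$transcripts
  rows <- list()
  if (length(txs) >= 2L) {
    for (i in seq_len(length(txs) - 1L)) {
      for (j in (i + 1L):length(txs)) {
        ev <- classify_pairwise(txs[[i]], txs[[j]])
        if (nrow(ev)) rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  events <- if (length(rows)) rbindlist(rows) else empty_events()
  if (nrow(events)) {
    setorder(events, site_key, tx_a, tx_b)
    events <- events[!duplicated(events$site_key), ]
  }
  cne <- find_cne(g, events)
  if (length(cne)) events <- rbindlist(c(list(events), cne))
  if (nrow(events) == 0L) {
    events <- empty_events()
    events[, event_id := character(0)]
    return(events)
  }
  events[, type_order := match(event_type, ALL_EVENT_TYPES)]
  setorder(events, type_order, exon_start, exon_end, site_key)
  events[, type_order := NULL]
  events[, event_id := sprintf("%s|%s|%d", gene_id, event_type,
                               seq_len(.N)), by = "event_type"]
  events[]
}

#' Annotate a list of genes
#'
#' @param genes List of `gene` objects.
#' @return Combined events data.table.
#' @export
annotate_genes <- function(genes) {
  ev <- rbindlist(lapply(genes, annotate_gene))
  if (nrow(ev) == 0L) {
    ev <- empty_events()
    ev[, event_id := character(0)]
  }
  ev[]
}

#' Remove events too close to transcript ends
#'
#' Drops events whose defining exon(s) overlap the first or last `window`
#' bp of the genomic span of either evidence transcript, i.e. exons within
#' `window` bp of the TSS or the transcript terminal site.
#'
#' @param events Events data.table.
#' @param genes The gene list the events were derived from (for transcript
#'   spans).
#' @param window Flank size in bp (default 2000; 0 disables the filter).
#' @return Filtered events data.table.
#' @export
filter_positional <- function(events, genes, window = 2000) {
  if (window == 0 || nrow(events) == 0L) return(events)
  tx_spans <- new.env(parent = emptyenv())
  for (g in genes) {
    for (t in g$transcripts) {
      assign(t$transcript_id, transcript_span(t), envir = tx_spans)
    }
  }
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    ex <- rbind(c(events$exon_start[i], events$exon_end[i]),
                c(events$exon2_start[i], events$exon2_end[i]))
    ex <- ex[!is.na(ex[, 1L]), , drop = FALSE]
    bad <- FALSE
    for (tid in unique(c(events$tx_a[i], events$tx_b[i]))) {
      sp <- get0(tid, envir = tx_spans)
      if (is.null(sp)) next
      w1 <- c(sp[1L], min(sp[2L], sp[1L] + window))
      w2 <- c(max(sp[1L], sp[2L] - window), sp[2L])
      if (any(overlaps(ex[, 1L], ex[, 2L], w1[1L], w1[2L])) ||
          any(overlaps(ex[, 1L], ex[, 2L], w2[1L], w2[2L]))) {
        bad <- TRUE
        break
      }
    }
    keep[i] <- !bad
  }
  events[keep, ]
}

# Acceptor/donor boundary coordinates of an exon, strand-aware.
exon_acceptor <- function(s, e, strand) if (strand == "+") s else e
exon_donor <- function(s, e, strand) if (strand == "+") e else s

#' Select the analyzed splice sites of annotated events
#'
#' ES and CNE contribute the acceptor and donor of the event exon. A3SS and
#' A5SS contribute the sites of the longer of the two alternative exons
#' (ties resolved to the 5'-most exon in transcript orientation, with a
#' warning). IR contributes the donor at the retained intron's 5' boundary
#' and the acceptor at its 3' boundary. ME contributes the acceptor and
#' donor of each of its two exons, counted as independent sites.
#'
#' @param events Events data.table with `event_id`.
#' @return Sites data.table: `site_id`, `event_id`, `event_type`, `gene_id`,
#'   `chrom`, `strand`, `kind` (acceptor/donor), `pos` (0-based boundary
#'   coordinate), `exon_ordinal`.
#' @export
select_splice_sites <- function(events) {
  rows <- vector("list", nrow(events))
  n_ties <- 0L
  for (i in seq_len(nrow(events))) {
    type <- events$event_type[i]
    strand <- events$strand[i]
    e1 <- c(events$exon_start[i], events$exon_end[i])
    e2 <- c(events$exon2_start[i], events$exon2_end[i])
    site_exons <- switch(
      type,
      ES = , CNE = list(e1),
      ME = list(e1, e2),
      A3SS = , A5SS = {
        l1 <- e1[2L] - e1[1L]; l2 <- e2[2L] - e2[1L]
        if (l1 > l2) list(e1)
        else if (l2 > l1) list(e2)
        else {
          n_ties <- n_ties + 1L
          # tie: keep the 5'-most exon in transcript orientation
          if (strand == "+") {
            list(if (e1[1L] <= e2[1L]) e1 else e2)
          } else {
            list(if (e1[2L] >= e2[2L]) e1 else e2)
          }
        }
      },
      IR = NULL)
    if (type == "IR") {
      ri <- c(events$intron_start[i], events$intron_end[i])
      acc <- if (strand == "+") ri[2L] else ri[1L]
      don <- if (strand == "+") ri[1L] else ri[2L]
      rows[[i]] <- data.table(site_index = 1L,
                              kind = c("acceptor", "donor"),
                              pos = c(acc, don))
    } else {
      rows[[i]] <- rbindlist(lapply(seq_along(site_exons), function(j) {
        ex <- site_exons[[j]]
        data.table(site_index = j,
                   kind = c("acceptor", "donor"),
                   pos = c(exon_acceptor(ex[1L], ex[2L], strand),
                           exon_donor(ex[1L], ex[2L], strand)))
      }))
    }
    rows[[i]][, `:=`(event_id = events$event_id[i], event_type = type,
                     gene_id = events$gene_id[i], chrom = events$chrom[i],
                     strand = strand,
                     exon_ordinal = events$exon_ordinal[i])]
  }
  if (n_ties > 0L) {
    ep_warn(sprintf(
      "%d A3SS/A5SS event(s) with equal-length alternative exons; kept the 5'-most exon's sites",
      n_ties))
  }
  sites <- rbindlist(rows)
  if (nrow(sites) == 0L) {
    return(data.table(site_id = character(0), event_id = character(0),
                      event_type = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      kind = character(0), pos = numeric(0),
                      exon_ordinal = integer(0)))
  }
  sites[, site_id := paste(event_id, site_index, sep = ".")]
  sites[, site_index := NULL]
  setcolorder(sites, c("site_id", "event_id", "event_type", "gene_id",
                       "chrom", "strand", "kind", "pos", "exon_ordinal"))
  sites[]
}

#' Write events to TSV
#'
#' One row per (event, splice-site pair): ME events occupy two rows, one per
#' exon, reflecting their independent site accounting.
#'
#' @param events Events data.table with `event_id`.
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  sites <- select_splice_sites(events)
  wide <- data.table::dcast(sites, site_id + event_id + event_type + gene_id +
                              chrom + strand + exon_ordinal ~ kind,
                            value.var = "pos")
  ev <- merge(wide,
              events[, c("event_id", "tx_a", "tx_b")], by = "event_id")
  ev[, evidence := paste(tx_a, tx_b, sep = ",")]
  ev <- ev[, c("event_id", "event_type", "gene_id", "chrom", "strand",
               "acceptor", "donor", "exon_ordinal", "evidence")]
  data.table::setnames(ev, c("acceptor", "donor"),
                       c("acceptor_pos", "donor_pos"))
  setorder(ev, event_id)
  fwrite(ev, path, sep = "\t")
  invisible(path)
}

#' Write splice sites as BED6
#'
#' Each site becomes a 1-bp interval at its boundary's right-hand base;
#' the name encodes `event_id:kind`.
#'
#' @param sites Sites table from [select_splice_sites()].
#' @param path Output path.
#' @export
sites_to_bed <- function(sites, path) {
  bed <- data.table(chrom = sites$chrom, start = as.integer(sites$pos),
                    end = as.integer(sites$pos) + 1L,
                    name = paste(sites$event_id, sites$kind, sep = ":"),
                    score = 0L, strand = sites$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
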