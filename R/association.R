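# ASE-vs-CNE association tests and the signed log-p matrix.
#
# For every (feature, event type, bin) cell, the per-site observations of
# the event type are compared against the CNE observations of the same
# feature and bin with a one-tailed Welch t-test; the tail is the direction
# of the observed mean difference, so each cell reports one direction and
# one p-value. Cell lines pool as independent observations before testing:
# consistent patterns across lines sharpen the p-value, inconsistent ones
# dilute it. Bonferroni correction uses the number of populated cells as
# the family size by default (logged and configurable).

#' One-tailed Welch t-test with post-hoc direction
#'
#' Compares the mean level in the event group against the reference (CNE)
#' group. The reported direction is the sign of `mean(ase) - mean(cne)` and
#' the p-value is one-tailed in that direction using Welch's
#' unequal-variance statistic. Exactly equal means give p = 0.5 with the
#' direction resolved to `higher_in_CNE` (deterministic tie convention);
#' two constant, equal samples are additionally flagged degenerate.
#'
#' @param ase_values,cne_values Numeric vectors, each of length >= 2, with
#'   nonzero variance in at least one of them (unless both are constant and
#'   equal).
#' @return List: `direction`, `p_raw`, `mean_ase`, `mean_cne`, `n_ase`,
#'   `n_cne`, `statistic`, `df`, `degenerate`.
#' @export
one_tailed_t <- function(ase_values, cne_values) {
  ase_values <- ase_values[is.finite(ase_values)]
  cne_values <- cne_values[is.finite(cne_values)]
  if (length(ase_values) < 2L || length(cne_values) < 2L) {
    stop("insufficient data: each group needs >= 2 finite observations")
  }
  m_ase <- mean(ase_values)
  m_cne <- mean(cne_values)
  base <- list(mean_ase = m_ase, mean_cne = m_cne,
               n_ase = length(ase_values), n_cne = length(cne_values))
  if (m_ase == m_cne) {
    degen <- stats::var(ase_values) == 0 && stats::var(cne_values) == 0
    return(c(base, list(direction = "higher_in_CNE", p_raw = 0.5,
                        statistic = 0, df = NA_real_, degenerate = degen)))
  }
  direction <- if (m_ase > m_cne) "higher_in_ASE" else "higher_in_CNE"
  if (stats::var(ase_values) == 0 && stats::var(cne_values) == 0) {
    # constant but unequal groups: infinitely significant in the limit
    return(c(base, list(direction = direction,
                        p_raw = .Machine$double.xmin,
                        statistic = sign(m_ase - m_cne) * Inf,
                        df = NA_real_, degenerate = TRUE)))
  }
  alt <- if (direction == "higher_in_ASE") "greater" else "less"
  tt <- stats::t.test(ase_values, cne_values, alternative = alt,
                      var.equal = FALSE)
  c(base, list(direction = direction, p_raw = unname(tt$p.value),
               statistic = unname(tt$statistic),
               df = unname(tt$parameter), degenerate = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw p-value(s).
#' @param m Family size (number of tests), >= 1.
#' @return `min(1, m * p_raw)`, vectorized.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot_scalar_count(m, "m")
  pmin(1, m * p_raw)
}

#' Significance call
#'
#' Strictly-smaller-than-alpha rule: an adjusted p of exactly `alpha` is
#' not significant.
#'
#' @param p_adj Adjusted p-value(s).
#' @param alpha Threshold (default 1e-2).
#' @return Logical vector.
#' @export
significance_call <- function(p_adj, alpha = 1e-2) {
  p_adj < alpha
}

#' ChIP-input correction
#'
#' Subtracts the input-track signal from the feature signal in the same bin
#' and cell line; negative corrected values are preserved (many splice
#' sites have no ChIP signal, so flooring would bias the comparison).
#'
#' @param value Feature signal.
#' @param input_value Input-track signal for the same bin/cell line.
#' @return `value - input_value`.
#' @export
correct_input <- function(value, input_value) {
  value - input_value
}

#' Nucleosome-occupancy correction
#'
#' Divides the feature signal by the nucleosome signal plus a pseudocount
#' (histone marks are only meaningful where nucleosomes exist). A constant
#' nucleosome track leaves all t-test p-values unchanged (scale
#' invariance).
#'
#' @param value Feature signal.
#' @param nuc_value Nucleosome signal for the same bin.
#' @param pseudocount Positive stabilizer for zero-occupancy bins
#'   (default 1).
#' @return `value / (nuc_value + pseudocount)`.
#' @export
correct_nucleosome <- function(value, nuc_value, pseudocount = 1) {
  if (any(pseudocount <= 0)) stop("pseudocount must be > 0")
  value / (nuc_value + pseudocount)
}

#' Apply a correction to an observation table
#'
#' Joins the reference levels (input or nucleosome, themselves produced by
#' [collect_levels()] on the reference track) onto the feature observations
#' by site, bin and cell line, and applies the requested correction.
#' `input_subtract` requires a reference for every cell line present in the
#' observations; `nucleosome_divide` accepts a single-cell-line reference
#' (e.g. one occupancy map) which is then recycled across all cell lines.
#'
#' @param levels Observations from [collect_levels()].
#' @param ref_levels Reference observations (one feature).
#' @param mode `"none"`, `"input_subtract"` or `"nucleosome_divide"`.
#' @param pseudocount Used by `nucleosome_divide` (default 1).
#' @return Corrected observation table.
#' @export
apply_correction <- function(levels, ref_levels,
                             mode = c("none", "input_subtract",
                                      "nucleosome_divide"),
                             pseudocount = 1) {
  mode <- match.arg(mode)
  if (mode == "none") return(levels)
  recycle <- mode == "nucleosome_divide" &&
    length(unique(ref_levels$cell_line)) == 1L
  ref_key <- if (recycle) {
    paste(ref_levels$site_id, ref_levels$bin)
  } else {
    paste(ref_levels$site_id, ref_levels$bin, ref_levels$cell_line)
  }
  obs_key <- if (recycle) {
    paste(levels$site_id, levels$bin)
  } else {
    paste(levels$site_id, levels$bin, levels$cell_line)
  }
  ref_value <- ref_levels$value[match(obs_key, ref_key)]
  if (anyNA(ref_value)) {
    if (mode == "input_subtract") {
      stop("missing input-track values for some cell line/bin combinations")
    }
    stop("missing nucleosome-track values for some bins")
  }
  out <- data.table::copy(levels)
  if (mode == "input_subtract") {
    out[, value := correct_input(value, ref_value)]
  } else {
    out[, value := correct_nucleosome(value, ref_value, pseudocount)]
  }
  out[]
}

#' Test every (feature, event type, bin) cell against CNE
#'
#' Pools observations across cell lines, drops missing observations (e.g.
#' methylation bins without CpG sites), and runs [one_tailed_t()] per cell
#' with CNE observations of the same feature and bin as the reference.
#' Bonferroni family size defaults to the number of populated (tested)
#' cells.
#'
#' @param levels Observations from [collect_levels()] (must contain CNE
#'   events).
#' @param m Bonferroni family size; `NULL` (default) uses the number of
#'   tested cells.
#' @param alpha Significance threshold on adjusted p (default 1e-2).
#' @return data.table of class `association_results`: one row per tested
#'   cell with counts, means, `direction`, `p_raw`, `p_adj`, `significant`.
#' @export
test_associations <- function(levels, m = NULL, alpha = 1e-2) {
  obs <- levels[!levels$missing, ]
  cne <- obs[obs$event_type == "CNE", ]
  if (nrow(cne) == 0L) stop("no CNE observations: reference group is empty")
  ase <- obs[obs$event_type != "CNE", ]
  cells <- unique(ase[, c("feature", "event_type", "bin")])
  setorder(cells, feature, event_type, bin)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- ase[ase$feature == cells$feature[i] &
               ase$event_type == cells$event_type[i] &
               ase$bin == cells$bin[i], ]$value
    c0 <- cne[cne$feature == cells$feature[i] &
                cne$bin == cells$bin[i], ]$value
    if (length(a) < 2L || length(c0) < 2L) next
    tt <- one_tailed_t(a, c0)
    rows[[i]] <- data.table(
      feature = cells$feature[i], event_type = cells$event_type[i],
      bin = cells$bin[i], n_ase = tt$n_ase, n_cne = tt$n_cne,
      mean_ase = tt$mean_ase, mean_cne = tt$mean_cne,
      direction = tt$direction, p_raw = tt$p_raw,
      degenerate = tt$degenerate)
  }
  res <- rbindlist(rows)
  if (nrow(res) == 0L) stop("no testable cells (insufficient observations)")
  family <- m %||% nrow(res)
  ep_log(sprintf("Bonferroni family size m = %d over %d tested cell(s)",
                 as.integer(family), nrow(res)))
  res[, p_adj := bonferroni(p_raw, family)]
  res[, significant := significance_call(p_adj, alpha)]
  class(res) <- c("association_results", class(res))
  res[]
}

#' Build the signed log-p association matrix
#'
#' Rows are features; columns are (event type x bin), ordered ES, ME, A3SS,
#' A5SS, IR by acceptor-intronic, acceptor-exonic, donor-exonic,
#' donor-intronic. Entries are `-log10(p)` when the feature is higher in
#' the ASE and `log10(p)` when higher in CNE, so positive entries always
#' mean ASE-enriched. Cells absent from `results` are `NA` (imputed to 0 by
#' the clustering step).
#'
#' @param results From [test_associations()].
#' @param adjusted Use `p_adj` (default) or raw p-values (the variant used
#'   when comparing correction modes).
#' @return Numeric matrix with feature rownames and `event.bin` colnames.
#' @export
build_matrix <- function(results, adjusted = TRUE) {
  p <- if (adjusted) results$p_adj else results$p_raw
  entry <- ifelse(results$direction == "higher_in_ASE", -log10(p), log10(p))
  features <- sort(unique(results$feature))
  cols <- as.vector(outer(BIN_LEVELS, EVENT_TYPES,
                          function(b, t) paste(t, b, sep = ".")))
  mat <- matrix(NA_real_, nrow = length(features), ncol = length(cols),
                dimnames = list(features, cols))
  key <- paste(results$event_type, results$bin, sep = ".")
  for (i in seq_len(nrow(results))) {
    if (!key[i] %in% cols) next
    if (!is.na(mat[results$feature[i], key[i]])) {
      stop("duplicate cell in results: ", results$feature[i], " ", key[i])
    }
    mat[results$feature[i], key[i]] <- entry[i]
  }
  mat
}

#' Write the association matrix to TSV
#'
#' @param mat Matrix from [build_matrix()].
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table(feature = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
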