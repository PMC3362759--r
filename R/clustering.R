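# Clustering of epigenetic features and AS-type classes from the signed
# log-p matrix, plus a classical MDS embedding. K-means runs directly on
# the signed log-p row vectors under Euclidean geometry; k defaults to 4
# for features and 2 for AS types.

#' K-means clustering of matrix rows
#'
#' Runs `stats::kmeans` with Euclidean geometry and `restarts` independent
#' initializations drawn from a seeded generator, returning the assignment
#' with the smallest total within-cluster sum of squares. Missing cells are
#' imputed to 0 ("no evidence either way", logged). Cluster labels are
#' canonicalized by ordering centroids along the data's first principal
#' coordinate, so a given seed always yields the same labelling.
#'
#' @param x Numeric matrix, rows = items to cluster.
#' @param k Number of clusters.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param restarts Independent initializations (default 25).
#' @return List of class `cluster_assignment`: `items`, `labels` (named
#'   integer vector in `1..k`), `k`, `seed`, `wcss`, `centers`.
#' @export
kmeans_cluster <- function(x, k, seed, restarts = 25) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  if (k > nrow(x)) stop("k exceeds the number of items")
  if (anyNA(x)) {
    ep_log(sprintf("imputing %d missing matrix cell(s) to 0", sum(is.na(x))))
    x[is.na(x)] <- 0
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct == k) {
    # exact solution: each distinct row is its own centroid (WCSS from
    # duplicates only); stats::kmeans declines k == n, so assign directly
    key <- apply(x, 1L, paste, collapse = "\r")
    centers <- unique(x)
    pc1 <- tryCatch(stats::prcomp(x, center = TRUE, scale. = FALSE)$rotation[, 1L],
                    error = function(e) rep(1 / sqrt(ncol(x)), ncol(x)))
    ord <- order(as.vector(centers %*% pc1))
    centers <- centers[ord, , drop = FALSE]
    ckey <- apply(centers, 1L, paste, collapse = "\r")
    labels <- stats::setNames(match(key, ckey), rownames(x))
    rownames(centers) <- seq_len(k)
    return(structure(list(items = rownames(x), labels = labels, k = k,
                          seed = seed, wcss = 0, centers = centers),
                     class = "cluster_assignment"))
  }
  if (n_distinct < k) {
    # degenerate: fewer distinct points than clusters; any k-partition that
    # co-clusters duplicates has equal (zero extra) WCSS, so assign
    # duplicates their distinct-row index deterministically
    ep_log(sprintf(
      "degenerate clustering: %d distinct row(s) for k = %d", n_distinct, k))
    key <- apply(x, 1L, paste, collapse = "\r")
    labels <- stats::setNames(match(key, unique(key)), rownames(x))
    centers <- unique(x)
    rownames(centers) <- seq_len(nrow(centers))
    return(structure(list(items = rownames(x), labels = labels, k = k,
                          seed = seed, wcss = 0, centers = centers),
                     class = "cluster_assignment"))
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100))
  # canonical label order: centroid projection on the first principal axis
  pc1 <- tryCatch(stats::prcomp(x, center = TRUE, scale. = FALSE)$rotation[, 1L],
                  error = function(e) rep(1 / sqrt(ncol(x)), ncol(x)))
  proj <- as.vector(km$centers %*% pc1)
  relabel <- match(seq_len(k), order(proj))
  labels <- stats::setNames(relabel[km$cluster], rownames(x))
  centers <- km$centers[order(proj), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(items = rownames(x), labels = labels, k = k, seed = seed,
                 wcss = km$tot.withinss, centers = centers),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment k=%d seed=%s wcss=%.4g>\n", x$k,
              format(x$seed), x$wcss))
  print(x$labels)
  invisible(x)
}

#' Cluster AS types from the association matrix
#'
#' Each AS type is represented by the concatenation of its (feature x bin)
#' signed log-p entries; the resulting 5-row matrix is clustered with
#' [kmeans_cluster()] (k = 2 recovers the exon-skipping-related class
#' {ES, ME} versus the splice-site-selection class {A3SS, A5SS, IR} when
#' their association signs oppose).
#'
#' @param mat Matrix from [build_matrix()] (columns named `type.bin`).
#' @param k Number of classes (default 2).
#' @param seed,restarts As in [kmeans_cluster()].
#' @return A `cluster_assignment` over the AS types.
#' @export
cluster_as_types <- function(mat, k = 2, seed, restarts = 25) {
  types <- unique(sub("\\..*$", "", colnames(mat)))
  rows <- t(vapply(types, function(ty) {
    as.vector(mat[, grep(paste0("^", ty, "\\."), colnames(mat)), drop = FALSE])
  }, numeric(nrow(mat) * length(BIN_LEVELS))))
  rownames(rows) <- types
  if (all(stats::dist(ifelse(is.na(rows), 0, rows)) == 0)) {
    ep_log("all AS-type vectors identical: clustering is degenerate")
  }
  kmeans_cluster(rows, k = k, seed = seed, restarts = restarts)
}

#' Classical multidimensional scaling of matrix rows
#'
#' Double-centered eigendecomposition of the Euclidean distance matrix
#' (`stats::cmdscale`); the sign of each returned axis is fixed by making
#' its largest-magnitude coordinate positive, so embeddings are
#' reproducible. If the configuration has rank below `dims`, the available
#' dimensions are returned with a log message.
#'
#' @param mat Numeric matrix, rows = items (missing cells imputed to 0).
#' @param dims Target dimensionality (default 2).
#' @return Numeric matrix of item coordinates (rownames preserved).
#' @export
classical_mds <- function(mat, dims = 2) {
  x <- as.matrix(mat)
  if (anyNA(x)) x[is.na(x)] <- 0
  if (nrow(x) < dims + 1) stop("need at least dims + 1 items")
  fit <- stats::cmdscale(stats::dist(x), k = dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims) {
    ep_log(sprintf("configuration rank %d < %d requested dims",
                   ncol(pts), dims))
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  pts
}

#' Write a cluster assignment to TSV
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(assignment, path) {
  dt <- data.table(item = assignment$items,
                   label = unname(assignment$labels[assignment$items]),
                   k = assignment$k, seed = assignment$seed,
                   wcss = assignment$wcss)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
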