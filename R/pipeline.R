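# Pipeline orchestration: a single configuration drives the simulate /
# annotate / profile / associate / cluster stages, each independently
# runnable and writing deterministic, provenance-stamped TSVs. The
# config is a plain named list (or YAML file) validated by
# pipeline_config(); every output file's first line records the config
# hash and seed, so two runs from the same fixture and config are byte
# identical.

pipeline_defaults <- function() {
  list(bin_length = 100, extension = 200, smoothing_window = 147,
       tss_buffer = 2000, alpha = 1e-2, k_features = 4, k_types = 2,
       restarts = 25, include_sequence_features = TRUE)
}

#' Build a validated pipeline configuration
#'
#' @param config Named list or path to a YAML file with entries: `seed`
#'   (integer, mandatory), `out_dir`, `paths` (`genome`, `gtf`,
#'   `methylation` -- the last two optional depending on the stages run),
#'   `manifest` (`feature -> cell_line -> BED path` for read features),
#'   `correction` (`mode`, `pseudocount`, `input` per cell line,
#'   `nucleosome`), `params` (overrides of bin_length = 100,
#'   extension = 200, smoothing_window = 147, tss_buffer = 2000,
#'   alpha = 1e-2, k_features = 4, k_types = 2, restarts = 25), and
#'   optionally `simulate` (arguments for [sim_config()]).
#' @return List of class `pipeline_config` with defaults filled in and a
#'   stable `hash`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  if (is.null(config$out_dir)) stop("config$out_dir is mandatory")
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  if (any(unlist(params[c("bin_length", "extension", "smoothing_window",
                          "k_features", "k_types", "restarts")]) < 1)) {
    stop("pipeline parameters must be positive")
  }
  correction <- utils::modifyList(list(mode = "none", pseudocount = 1),
                                  config$correction %||% list())
  correction$mode <- match.arg(correction$mode,
                               c("none", "input_subtract", "nucleosome_divide"))
  if (correction$pseudocount <= 0) stop("correction pseudocount must be > 0")
  cfg <- list(seed = as.integer(config$seed), out_dir = config$out_dir,
              paths = config$paths %||% list(),
              manifest = config$manifest %||% list(),
              correction = correction, params = params,
              simulate = config$simulate %||% NULL)
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  for (p in unlist(cfg$manifest)) {
    if (!file.exists(p)) stop("manifest track does not exist: ", p)
  }
  cfg$hash <- object_hash(cfg[c("seed", "paths", "manifest", "correction",
                                "params", "simulate")])
  structure(cfg, class = "pipeline_config")
}

stamp_write <- function(dt, path, cfg) {
  writeLines(sprintf("# episplice config=%s seed=%d", cfg$hash, cfg$seed),
             path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a provenance-stamped pipeline TSV
#'
#' @param path File written by a pipeline stage (first line is the stamp).
#' @return data.table.
#' @export
read_stamped_tsv <- function(path) {
  fread(path, sep = "\t", skip = 1L, header = TRUE)
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$out_dir
}

#' Stage: generate a synthetic fixture
#'
#' Runs the synthetic-data generator under `config$simulate` (with the
#' pipeline seed) and writes the fixture plus truth tables under
#' `out_dir/fixture`.
#'
#' @param cfg A `pipeline_config` with a `simulate` entry.
#' @return The `simulation` (with `$paths`), invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$simulate)) stop("config has no `simulate` section")
  ensure_out_dir(cfg)
  args <- cfg$simulate
  args$seed <- args$seed %||% cfg$seed
  scfg <- do.call(sim_config, args)
  sim <- generate_fixture(scfg, file.path(cfg$out_dir, "fixture"))
  ep_log(sprintf("simulated %d gene(s) into %s", length(sim$genes),
                 file.path(cfg$out_dir, "fixture")))
  invisible(sim)
}

#' Stage: annotate AS events
#'
#' Reads the configured GTF, annotates events and CNEs, applies the
#' positional filter, selects splice sites, and writes `events.tsv` and
#' `splice_sites.tsv`.
#'
#' @param cfg A `pipeline_config`.
#' @return List with `genes`, `events` (filtered), `sites`, invisibly.
#' @export
run_annotate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$paths$gtf)) stop("config$paths$gtf is required")
  ensure_out_dir(cfg)
  genes <- read_gtf(cfg$paths$gtf, coding_only = TRUE)
  if (length(genes) == 0L) stop("no genes parsed from GTF")
  events <- annotate_genes(genes)
  filtered <- filter_positional(events, genes,
                                window = cfg$params$tss_buffer)
  n_drop <- nrow(events) - nrow(filtered)
  counts <- table(factor(filtered$event_type, levels = ALL_EVENT_TYPES))
  ep_log(sprintf("events after positional filter (%d dropped): %s", n_drop,
                 paste(names(counts), counts, sep = "=", collapse = " ")))
  if (nrow(filtered) == 0L) {
    ep_warn("no events remain after the positional filter")
  }
  sites <- select_splice_sites(filtered)
  stamp_write(filtered, file.path(cfg$out_dir, "events.tsv"), cfg)
  stamp_write(sites, file.path(cfg$out_dir, "splice_sites.tsv"), cfg)
  invisible(list(genes = genes, events = filtered, sites = sites))
}

# Assemble the feature -> cell_line -> track list from the config.
load_tracks <- function(cfg) {
  tracks <- list()
  if (isTRUE(cfg$params$include_sequence_features)) {
    if (!is.null(cfg$paths$genome)) {
      tracks[["CG"]] <- list(genome = track_sequence(cfg$paths$genome))
    }
    if (!is.null(cfg$paths$methylation)) {
      tracks[["mCG"]] <- list(combined = read_methylation(cfg$paths$methylation))
    }
  }
  for (f in names(cfg$manifest)) {
    tracks[[f]] <- lapply(cfg$manifest[[f]], load_reads,
                          extension = cfg$params$extension, label = f)
  }
  if (length(tracks) == 0L) stop("no feature tracks configured")
  tracks
}

collect_corrected_levels <- function(cfg, sites, tracks) {
  levels <- collect_levels(sites, tracks, bin_length = cfg$params$bin_length)
  mode <- cfg$correction$mode
  if (mode == "none") return(levels)
  read_features <- names(tracks)[vapply(tracks, function(x)
    x[[1L]]$kind == "reads", logical(1))]
  target <- levels[levels$feature %in% read_features, ]
  rest <- levels[!levels$feature %in% read_features, ]
  if (mode == "input_subtract") {
    if (is.null(cfg$correction$input)) {
      stop("input_subtract requires correction$input tracks per cell line")
    }
    ref_tracks <- list(input = lapply(cfg$correction$input, load_reads,
                                      extension = cfg$params$extension,
                                      label = "input"))
    missing_cl <- setdiff(unique(target$cell_line),
                          names(ref_tracks$input))
    if (length(missing_cl)) {
      stop("no input track for cell line(s): ",
           paste(missing_cl, collapse = ", "))
    }
  } else {
    if (is.null(cfg$correction$nucleosome)) {
      stop("nucleosome_divide requires a correction$nucleosome track")
    }
    ref_tracks <- list(nucleosome = list(
      combined = load_reads(cfg$correction$nucleosome,
                            extension = cfg$params$extension,
                            label = "nucleosome")))
  }
  ref_levels <- collect_levels(sites, ref_tracks,
                               bin_length = cfg$params$bin_length)
  corrected <- apply_correction(target, ref_levels, mode = mode,
                                pseudocount = cfg$correction$pseudocount)
  rbindlist(list(corrected, rest), use.names = TRUE)
}

#' Stage: association tests and signed log-p matrix
#'
#' Collects per-bin levels for every configured feature, applies the
#' configured correction to read features, tests every (feature, event
#' type, bin) cell against CNE, and writes `levels.tsv`,
#' `association_results.tsv` and `signed_logp_matrix.tsv`.
#'
#' @param cfg A `pipeline_config`.
#' @param annotation Output of [run_annotate()]; recomputed if `NULL`.
#' @return List with `levels`, `results`, `matrix`, invisibly.
#' @export
run_associate <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ensure_out_dir(cfg)
  ann <- annotation %||% run_annotate(cfg)
  if (!any(ann$events$event_type == "CNE")) {
    stop("no CNE events: association tests need a reference group")
  }
  tracks <- load_tracks(cfg)
  levels <- collect_corrected_levels(cfg, ann$sites, tracks)
  results <- test_associations(levels, alpha = cfg$params$alpha)
  mat <- build_matrix(results)
  stamp_write(levels, file.path(cfg$out_dir, "levels.tsv"), cfg)
  stamp_write(results, file.path(cfg$out_dir, "association_results.tsv"), cfg)
  mat_dt <- data.table(feature = rownames(mat))
  for (j in colnames(mat)) mat_dt[[j]] <- mat[, j]
  stamp_write(mat_dt, file.path(cfg$out_dir, "signed_logp_matrix.tsv"), cfg)
  invisible(list(levels = levels, results = results, matrix = mat))
}

#' Stage: cluster features and AS types
#'
#' K-means over the signed log-p matrix rows (features, k = `k_features`)
#' and over the AS-type vectors (k = `k_types`), plus a classical MDS
#' embedding of the features; writes `feature_clusters.tsv`,
#' `as_type_clusters.tsv` and `mds.tsv`.
#'
#' @param cfg A `pipeline_config`.
#' @param mat Signed log-p matrix; read from `out_dir` if `NULL`.
#' @return List with both `cluster_assignment`s and the MDS coordinates,
#'   invisibly.
#' @export
run_cluster <- function(cfg, mat = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ensure_out_dir(cfg)
  if (is.null(mat)) {
    dt <- read_stamped_tsv(file.path(cfg$out_dir, "signed_logp_matrix.tsv"))
    mat <- as.matrix(dt[, -1L])
    rownames(mat) <- dt$feature
  }
  if (nrow(mat) < cfg$params$k_features) {
    stop("fewer features than k_features")
  }
  feat <- kmeans_cluster(mat, k = cfg$params$k_features, seed = cfg$seed,
                         restarts = cfg$params$restarts)
  types <- cluster_as_types(mat, k = cfg$params$k_types, seed = cfg$seed,
                            restarts = cfg$params$restarts)
  emb <- if (nrow(mat) >= 3L) classical_mds(mat, dims = 2) else NULL
  write_stamped_clusters <- function(a, path) {
    stamp_write(data.table(item = a$items,
                           label = unname(a$labels[a$items]),
                           k = a$k, seed = a$seed, wcss = a$wcss),
                path, cfg)
  }
  write_stamped_clusters(feat, file.path(cfg$out_dir, "feature_clusters.tsv"))
  write_stamped_clusters(types, file.path(cfg$out_dir, "as_type_clusters.tsv"))
  if (!is.null(emb)) {
    stamp_write(data.table(item = rownames(emb),
                           dim1 = emb[, 1L],
                           dim2 = if (ncol(emb) > 1L) emb[, 2L] else 0),
                file.path(cfg$out_dir, "mds.tsv"), cfg)
  }
  invisible(list(features = feat, as_types = types, mds = emb))
}

#' Stage: position metaprofiles
#'
#' Per feature, event type and site kind, computes the -500..+200
#' (acceptor) and -200..+500 (donor) metaprofiles averaged across cell
#' lines; CG and mCG profiles are smoothed with the configured sliding
#' window (147 bp default), read profiles are not. Writes
#' `profiles.tsv` (long format). Event classes without sites are skipped
#' with a warning.
#'
#' @param cfg A `pipeline_config`.
#' @param annotation Output of [run_annotate()]; recomputed if `NULL`.
#' @return The long profile data.table, invisibly.
#' @export
run_profile <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ensure_out_dir(cfg)
  ann <- annotation %||% run_annotate(cfg)
  tracks <- load_tracks(cfg)
  out <- list()
  for (f in names(tracks)) {
    kind <- tracks[[f]][[1L]]$kind
    for (ty in intersect(ALL_EVENT_TYPES, unique(ann$sites$event_type))) {
      ss <- ann$sites[ann$sites$event_type == ty, ]
      for (sk in c("acceptor", "donor")) {
        if (!any(ss$kind == sk)) {
          ep_warn(sprintf("no %s sites for %s; profile skipped", sk, ty))
          next
        }
        prof <- position_profile_multi(ss, tracks[[f]], sk)
        if (kind %in% c("sequence_cpg", "methylation")) {
          prof <- smooth_profile(prof, window = cfg$params$smoothing_window,
                                 na.rm = TRUE)
        }
        prof[, `:=`(feature = f, event_type = ty)]
        out[[length(out) + 1L]] <- prof
      }
    }
  }
  profiles <- rbindlist(out)
  stamp_write(profiles, file.path(cfg$out_dir, "profiles.tsv"), cfg)
  invisible(profiles)
}

#' Run the full pipeline
#'
#' With a `simulate` section: generates the fixture, then points the
#' remaining stages at it (all planted read features enter the manifest).
#' Without one, runs annotate / profile / associate / cluster on the
#' configured inputs.
#'
#' @param cfg A `pipeline_config` (or list / YAML path accepted by
#'   [pipeline_config()]).
#' @return List with the outputs of each stage, invisibly.
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- run_simulate(cfg)
    cfg$paths$genome <- sim$paths$genome
    cfg$paths$gtf <- sim$paths$gtf
    cfg$paths$methylation <- sim$paths$methylation
    cfg$manifest <- sim$paths$reads
    if (!is.null(sim$paths$input)) cfg$correction$input <- sim$paths$input
    if (!is.null(sim$paths$nucleosome)) {
      cfg$correction$nucleosome <- sim$paths$nucleosome
    }
  }
  ann <- run_annotate(cfg)
  prof <- run_profile(cfg, annotation = ann)
  assoc <- run_associate(cfg, annotation = ann)
  clus <- run_cluster(cfg, mat = assoc$matrix)
  invisible(list(simulation = sim, annotation = ann, profiles = prof,
                 association = assoc, clusters = clus))
}
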