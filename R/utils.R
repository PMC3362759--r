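# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom data.table data.table as.data.table setDT setkey setkeyv
#'   rbindlist fread fwrite setorder setorderv setcolorder :=
NULL

# Quiet, prefix-tagged logging; suppressible via options(episplice.verbose = FALSE).
ep_log <- function(...) {
  if (isTRUE(getOption("episplice.verbose", TRUE))) {
    message("[episplice] ", ...)
  }
  invisible(NULL)
}

ep_warn <- function(...) {
  warning(..., call. = FALSE)
  invisible(NULL)
}

# Half-open interval overlap (0-based coordinates throughout the package).
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %d", name, min), call. = FALSE)
  }
  invisible(TRUE)
}

# Stable md5 of an arbitrary R object (used to stamp pipeline outputs).
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
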