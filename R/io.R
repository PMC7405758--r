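#' Write / read a trial table
#'
#' Trial tables travel as tab-separated text, one row per trial.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials` returns the tibble; `write_trials` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read an eye trace
#'
#' Traces travel as tab-separated time series (`t_ms`, `x_deg`, `valid`);
#' event annotations and metadata are not round-tripped (they are
#' re-derivable by detection).
#'
#' @param trace An [eye_trace()].
#' @param path File path.
#' @return `read_trace` returns an [eye_trace()]; `write_trace` its path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_tsv(tibble::as_tibble(trace[, c("t_ms", "x_deg", "valid")]),
                   path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  eye_trace(df$t_ms, df$x_deg, as.logical(df$valid))
}

#' Write a run manifest
#'
#' Seeds, settings, and ground-truth observer parameters as JSON.
#'
#' @param manifest List (e.g. `generate_dataset()$manifest`).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
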