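# Plain-text interchange formats: long CSVs for curves, peaks, profiles and
# calls, plus a JSON sidecar that records the configuration and seed so any
# simulated data set can be regenerated exactly.

#' Read and write melt curves, MLPA profiles, peaks and calls as CSV
#'
#' @param curves,profiles,peaks,calls Tibbles produced by the corresponding
#'   package functions.
#' @param path File path.
#' @return Readers return a tibble; writers invisibly return `path`.
#' @name smn_io
NULL

#' @rdname smn_io
#' @export
write_melt_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname smn_io
#' @export
read_melt_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    temperature_c = readr::col_double(),
                    fluorescence = readr::col_double()))
}

#' @rdname smn_io
#' @export
write_mlpa_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname smn_io
#' @export
read_mlpa_profiles <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    probe_id = readr::col_character(),
                    target_class = readr::col_character(),
                    height = readr::col_double()))
}

#' @rdname smn_io
#' @export
write_peaks <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' @rdname smn_io
#' @export
write_tier1_calls <- function(calls, path) {
  readr::write_csv(calls, path)
  invisible(path)
}

#' Write a run manifest (configuration + seed) as JSON
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed of the run.
#' @param path File path for the JSON sidecar.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(config, seed, path) {
  jsonlite::write_json(list(seed = seed, config = unclass(config)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
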