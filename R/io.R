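#' @name cli_io
#' @title Tabular readers/writers and run provenance
#'
#' @description
#' The shared tabular dialect: UTF-8, tab-separated, header row, times in
#' ms, missing pupil samples as the sentinel −1. Writers and readers
#' round-trip exactly on valid files; malformed rows are rejected with their
#' line number.
NULL

#' Write / read a binocular sample table
#'
#' Columns `t_ms`, `left_mm`, `right_mm`; timestamps strictly increasing,
#' blinks as −1.
#'
#' @param samples data frame with the columns above.
#' @param path file path.
#' @return `read_samples()` returns a tibble; `write_samples()` its path,
#'   invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(all(c("t_ms", "left_mm", "right_mm") %in% names(samples)))
  write.table(samples, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("t_ms", "left_mm", "right_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("sample file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(diff(df$t_ms) <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone timestamp at line %d of %s",
                 bad[1] + 2L, path), call. = FALSE)  # +1 header, +1 next row
  }
  tibble::as_tibble(df)
}

#' Convert a raw sample table to a pupil series for one eye
#'
#' The sentinel −1 and non-finite entries are masked; the sampling rate is
#' inferred from the median timestamp step unless given.
#'
#' @param samples tibble from [read_samples()] or a `synth_session`.
#' @param eye `"left"` or `"right"`.
#' @param fs_hz optional explicit rate.
#' @return a [pupil_series()].
#' @export
samples_to_series <- function(samples, eye = c("left", "right"), fs_hz = NULL) {
  eye <- match.arg(eye)
  v <- samples[[paste0(eye, "_mm")]]
  fs <- fs_hz %||% (1000 / median(diff(samples$t_ms)))
  pupil_series(v, fs, t0_ms = samples$t_ms[1])
}

#' Write / read an events table
#'
#' Long-format events dialect: `onset_ms`, `duration_ms`, `trial`,
#' `condition`, `event_type` (see [schedule_events()]).
#'
#' @param events data frame in the dialect above.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  need <- c("onset_ms", "duration_ms", "trial", "condition", "event_type")
  stopifnot(all(need %in% names(events)))
  write.table(events[, need], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("onset_ms", "duration_ms", "trial", "condition", "event_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("events file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$onset_ms))) {
    stop(sprintf("malformed onset at line %d of %s",
                 which(!is.finite(df$onset_ms))[1] + 1L, path), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write / read R-peak times as single-column text (ms)
#'
#' @param peaks_ms numeric vector of strictly increasing peak times.
#' @param path file path.
#' @export
write_peaks <- function(peaks_ms, path) {
  write.table(format(peaks_ms, digits = 12, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  p <- scan(path, what = numeric(), quiet = TRUE)
  bad <- which(diff(p) <= 0)
  if (length(bad)) {
    stop(sprintf("non-increasing R-peak time at line %d of %s", bad[1] + 1L,
                 path), call. = FALSE)
  }
  p
}

#' Write an analysis report with provenance
#'
#' Serializes a named list of results as JSON together with a provenance
#' record (seed, configuration hash via serialization checksum, package
#' version, timestamp).
#'
#' @param results named list of results (numbers, vectors, tibbles).
#' @param path output path.
#' @param seed the seed governing the run's randomness.
#' @param config optional configuration list recorded alongside.
#' @export
write_report <- function(results, path, seed = NA, config = NULL) {
  prov <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("pupilbf")),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_checksum = if (is.null(config)) NA else
      sum(utf8ToInt(paste(deparse(config), collapse = "")))
  )
  jsonlite::write_json(list(provenance = prov, results = results), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
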