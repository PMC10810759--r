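#' Regularly sampled pupil-diameter time series
#'
#' Container for a regularly indexed pupil-diameter trace with an explicit
#' validity mask. Sample `i` is taken at `t0_ms + (i - 1) * 1000 / fs_hz`.
#' Masked (invalid) entries carry no numeric meaning: filters in this package
#' only ever mask samples, they never alter raw values (until resampling).
#'
#' @param values_mm numeric vector of pupil diameters in mm. The blink
#'   sentinel −1 and `NA` are marked invalid automatically.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param t0_ms time of the first sample in ms.
#' @param valid optional logical vector, `TRUE` where the sample is usable.
#'   Defaults to finite, non-sentinel values.
#' @return an object of class `pupil_series`.
#' @export
pupil_series <- function(values_mm, fs_hz, t0_ms = 0, valid = NULL) {
  values_mm <- as.numeric(values_mm)
  if (is.null(valid)) {
    valid <- is.finite(values_mm) & values_mm != -1
  }
  valid <- as.logical(valid)
  if (length(valid) != length(values_mm)) {
    stop("`valid` and `values_mm` must have the same length", call. = FALSE)
  }
  valid[is.na(valid)] <- FALSE
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values_mm = values_mm, valid = valid,
         fs_hz = as.numeric(fs_hz), t0_ms = as.numeric(t0_ms)),
    class = "pupil_series"
  )
}

#' @export
#' @method length pupil_series
length.pupil_series <- function(x) length(x$values_mm)

#' Sample times of a pupil series
#'
#' @param s a [pupil_series()].
#' @return numeric vector of sample times in ms.
#' @export
ps_times <- function(s) {
  stopifnot(inherits(s, "pupil_series"))
  s$t0_ms + (seq_along(s$values_mm) - 1) * 1000 / s$fs_hz
}

#' @export
#' @method print pupil_series
print.pupil_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf(
    "<pupil_series> %d samples @ %g Hz, t0 = %g ms, %.1f%% valid\n",
    n, x$fs_hz, x$t0_ms, if (n) 100 * mean(x$valid) else NA_real_
  ))
  invisible(x)
}

#' @export
#' @method as.data.frame pupil_series
as.data.frame.pupil_series <- function(x, ...) {
  data.frame(t_ms = ps_times(x), mm = x$values_mm, valid = x$valid)
}

# Index range of samples with t in [from_ms, to_ms); empty -> integer(0).
# Computed arithmetically on the regular grid (O(1), exact at boundaries).
ps_window_idx <- function(s, from_ms, to_ms) {
  dt <- 1000 / s$fs_hz
  eps <- 1e-6
  lo <- ceiling((from_ms - s$t0_ms) / dt - eps) + 1
  hi <- floor((to_ms - s$t0_ms) / dt - eps) + 1
  lo <- max(lo, 1L)
  hi <- min(hi, length(s$values_mm))
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

# Time of sample index i.
ps_time_at <- function(s, i) s$t0_ms + (i - 1) * 1000 / s$fs_hz

# Replace the validity mask, keeping everything else.
ps_set_valid <- function(s, valid) {
  s$valid <- valid & s$valid
  s
}
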