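#' Pupil modulation index
#'
#' The modulation index is the average difference between baseline-corrected
#' Up and Down pupil traces over the modulation window,
#' `mean_t(Up(t) - Down(t))`; for full 15 s trials resampled to 1000 Hz the
#' average runs over n = 15,000 points. Positive values indicate
#' condition-appropriate regulation.
#'
#' @param up_mean_trace,down_mean_trace baseline-corrected condition-mean
#'   traces (numeric vectors of equal length, mm).
#' @return list of class `modulation_index` with `value_mm` and `n_samples`.
#' @export
modulation_index <- function(up_mean_trace, down_mean_trace) {
  if (length(up_mean_trace) != length(down_mean_trace)) {
    stop("traces must have equal length", call. = FALSE)
  }
  structure(list(value_mm = mean(up_mean_trace - down_mean_trace),
                 n_samples = length(up_mean_trace)),
            class = "modulation_index")
}

#' @export
#' @method print modulation_index
print.modulation_index <- function(x, ...) {
  cat(sprintf("Pupil modulation index: %.4f mm (n = %d samples)\n",
              x$value_mm, x$n_samples))
  invisible(x)
}

#' Downsample a pupil series to scanner volumes
#'
#' Averages the pupil signal within each repetition-time (TR) bin after
#' shifting the pupil signal forward by `shift_s` to compensate the
#' brain-to-pupil delay (implemented by subtracting `shift_s` from the pupil
#' timestamps: the pupil leads the haemodynamic response). Bins are
#' half-open `[k*TR, (k+1)*TR)` from the series start; bins left empty by
#' missing data are linearly interpolated across neighbouring bins.
#'
#' @param s a [pupil_series()] covering the run.
#' @param tr_s repetition time in seconds (> 0).
#' @param shift_s forward shift of the pupil signal in seconds, default 1.
#' @param n_volumes optional number of volumes; defaults to
#'   `floor(duration / TR)`.
#' @return numeric vector with one mean diameter per volume, usable as a
#'   GLM regressor.
#' @export
downsample_to_volumes <- function(s, tr_s, shift_s = 1.0, n_volumes = NULL) {
  stopifnot(inherits(s, "pupil_series"), tr_s > 0)
  dur_ms <- length(s) * 1000 / s$fs_hz
  if (dur_ms < tr_s * 1000) stop("run shorter than one TR", call. = FALSE)
  n_vol <- n_volumes %||% floor(dur_ms / (tr_s * 1000))
  t_shift <- ps_times(s) - s$t0_ms - shift_s * 1000
  bin <- floor(t_shift / (tr_s * 1000))
  keep <- s$valid & bin >= 0 & bin < n_vol
  sums <- tapply(s$values_mm[keep], factor(bin[keep], levels = 0:(n_vol - 1)),
                 mean)
  out <- as.numeric(sums)
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (!length(ok)) stop("no valid samples in any volume bin", call. = FALSE)
    out <- approx(ok, out[ok], xout = seq_len(n_vol), rule = 2)$y
  }
  out
}

#' Write a per-volume regressor as single-column text
#'
#' @param x numeric vector (one value per volume).
#' @param path output file.
#' @export
write_regressor <- function(x, path) {
  write.table(format(x, digits = 10, trim = TRUE), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
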