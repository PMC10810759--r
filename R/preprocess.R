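#' @name preprocess
#' @title Offline pupillometry cleaning cascade
#'
#' @description
#' The offline pipeline masks artifactual samples in a fixed order:
#' dilation-speed filter, trend-line filter (multipass), island removal,
#' binocular merge, resampling + zero-phase smoothing, trial rejection, and
#' baseline correction. Every filter only masks samples — raw values are
#' never altered until resampling.
NULL

# Unscaled median absolute deviation (no 1.4826 consistency constant).
mad_unscaled <- function(x) median(abs(x - median(x)))

#' Zero-phase Butterworth low-pass
#'
#' Forward-backward (zero-phase) Butterworth filtering with odd-reflection
#' padding at both ends so the edges are not distorted (an order-3 filter
#' applied twice gives an effective 6th-order magnitude response).
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate.
#' @param cutoff_hz low-pass cutoff, default 4.
#' @param order filter order per pass, default 3.
#' @return filtered vector, same length as `x`.
#' @export
zerophase_lowpass <- function(x, fs_hz, cutoff_hz = 4, order = 3) {
  n <- length(x)
  min_pad <- 3 * (order + 1)
  if (n <= min_pad) {
    stop("input shorter than the filter padding requirement", call. = FALSE)
  }
  if (cutoff_hz >= fs_hz / 2) return(x)
  np <- min(n - 1, ceiling(3 * fs_hz / cutoff_hz))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2))
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1):(np + n)]
}

#' Dilation-speed outlier filter
#'
#' For every valid sample the dilation speed is the larger of the normalized
#' absolute diameter changes toward its two valid temporal neighbours
#' (mm/ms, using actual inter-sample gaps). Samples whose speed exceeds
#' `median(speed) + mad_multiplier * MAD(speed)` (unscaled MAD, strict `>`)
#' are masked.
#'
#' @param s a [pupil_series()].
#' @param mad_multiplier default 12.
#' @param min_speed_mm_per_ms numerical floor on the masking threshold. When
#'   the speed MAD collapses to ~0 (noise-free or near-constant stretches)
#'   the adaptive threshold would mask every non-constant sample; speeds
#'   below this floor (default 0.001 mm/ms = 1 mm/s, well under the
#'   pupillary-light-reflex peak velocity) are never treated as artifacts.
#' @return a new `pupil_series` with the additional samples masked.
#' @export
dilation_speed_filter <- function(s, mad_multiplier = 12,
                                  min_speed_mm_per_ms = 0.001) {
  stopifnot(inherits(s, "pupil_series"))
  idx <- which(s$valid)
  if (length(idx) < 3) return(s)
  t <- ps_times(s)[idx]
  v <- s$values_mm[idx]
  fwd <- c(abs(diff(v)) / diff(t), NA)   # toward next valid neighbour
  bwd <- c(NA, abs(diff(v)) / diff(t))   # toward previous valid neighbour
  speed <- pmax(fwd, bwd, na.rm = TRUE)
  thr <- max(median(speed) + mad_multiplier * mad_unscaled(speed),
             min_speed_mm_per_ms)
  bad <- idx[speed > thr]
  s$valid[bad] <- FALSE
  s
}

#' Trend-line deviation filter (multipass)
#'
#' Each pass fits a trend line — the 4 Hz zero-phase low-pass of the linear
#' interpolation through currently valid samples — and masks valid samples
#' whose absolute deviation from it exceeds
#' `median + mad_multiplier * MAD` of the absolute deviations (strict `>`,
#' unscaled MAD). Exactly `passes` iterations are run.
#'
#' @param s a [pupil_series()].
#' @param passes number of passes, default 4.
#' @param mad_multiplier default 12.
#' @param cutoff_hz trend-line low-pass cutoff, default 4.
#' @param min_dev_mm numerical floor on the masking threshold. On data that
#'   the trend fits essentially perfectly the deviation MAD collapses to
#'   ~0 and pure float noise would be masked; deviations below this floor
#'   (default 0.01 mm, under eye-tracker quantization) are never treated as
#'   artifacts.
#' @return a new `pupil_series` with the additional samples masked.
#' @export
trendline_filter <- function(s, passes = 4, mad_multiplier = 12, cutoff_hz = 4,
                             min_dev_mm = 0.01) {
  stopifnot(inherits(s, "pupil_series"), passes >= 0)
  t_all <- ps_times(s)
  for (p in seq_len(passes)) {
    idx <- which(s$valid)
    if (length(idx) <= 2) {
      warning("trend line unfittable (<=2 valid samples); pass skipped")
      next
    }
    interp <- approx(t_all[idx], s$values_mm[idx], xout = t_all, rule = 2)$y
    trend <- zerophase_lowpass(interp, s$fs_hz, cutoff_hz)
    dev <- abs(s$values_mm[idx] - trend[idx])
    thr <- max(median(dev) + mad_multiplier * mad_unscaled(dev), min_dev_mm)
    s$valid[idx[dev > thr]] <- FALSE
  }
  s
}

#' Remove temporally isolated sample islands
#'
#' Contiguous valid runs no wider than `max_island_ms` that border masked
#' gaps wider than `min_gap_ms` on both sides (series edges count as gaps)
#' are masked. Widths are sample counts times the sampling interval.
#'
#' @param s a [pupil_series()].
#' @param max_island_ms maximum island width, default 50.
#' @param min_gap_ms gaps must be strictly wider than this, default 40.
#' @return a new `pupil_series`.
#' @export
remove_islands <- function(s, max_island_ms = 50, min_gap_ms = 40) {
  stopifnot(inherits(s, "pupil_series"))
  if (!length(s$valid)) return(s)
  dt <- 1000 / s$fs_hz
  r <- rle(s$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  widths <- r$lengths * dt
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (widths[i] > max_island_ms) next
    left <- if (i == 1) Inf else widths[i - 1]
    right <- if (i == length(r$values)) Inf else widths[i + 1]
    if (left > min_gap_ms && right > min_gap_ms) {
      s$valid[starts[i]:ends[i]] <- FALSE
    }
  }
  s
}

#' Merge left- and right-eye series into a mean series
#'
#' Where both eyes are valid the sample-wise mean is taken. Where exactly
#' one eye is valid, that eye's value is shifted by half the session-mean
#' inter-eye offset (computed over samples where both eyes are valid) so the
#' merged trace stays on the binocular-mean scale. Samples missing in both
#' eyes stay masked.
#'
#' @param left,right [pupil_series()] objects on an identical time base.
#' @return merged `pupil_series`.
#' @export
merge_eyes <- function(left, right) {
  stopifnot(inherits(left, "pupil_series"), inherits(right, "pupil_series"))
  if (length(left) != length(right) || left$fs_hz != right$fs_hz ||
      left$t0_ms != right$t0_ms) {
    stop("left and right series are not on the same time base", call. = FALSE)
  }
  both <- left$valid & right$valid
  offset <- if (any(both)) {
    mean(right$values_mm[both] - left$values_mm[both])
  } else {
    warning("no samples valid in both eyes; inter-eye offset assumed 0")
    0
  }
  out <- rep(NA_real_, length(left))
  out[both] <- (left$values_mm[both] + right$values_mm[both]) / 2
  lo <- left$valid & !right$valid
  out[lo] <- left$values_mm[lo] + offset / 2
  ro <- right$valid & !left$valid
  out[ro] <- right$values_mm[ro] - offset / 2
  pupil_series(out, left$fs_hz, left$t0_ms,
               valid = left$valid | right$valid)
}

#' Resample to a uniform rate and smooth with a zero-phase low-pass
#'
#' Valid samples are linearly interpolated onto the target grid (gaps are
#' bridged), then smoothed with a zero-phase Butterworth low-pass. Spans
#' that were missing in the input remain flagged in the output mask even
#' though interpolated values exist there.
#'
#' @param s a [pupil_series()] with at least 2 valid samples.
#' @param target_fs_hz target rate, default 1000.
#' @param cutoff_hz smoothing cutoff, default 4.
#' @param order filter order per pass, default 3.
#' @return a `pupil_series` at `target_fs_hz`; the mask marks originally
#'   missing spans.
#' @export
resample_smooth <- function(s, target_fs_hz = 1000, cutoff_hz = 4, order = 3) {
  stopifnot(inherits(s, "pupil_series"))
  idx <- which(s$valid)
  if (length(idx) < 2) stop("need at least 2 valid samples to resample",
                            call. = FALSE)
  t_all <- ps_times(s)
  n_out <- round(length(s) * target_fs_hz / s$fs_hz)
  t_out <- s$t0_ms + (seq_len(n_out) - 1) * 1000 / target_fs_hz
  y <- approx(t_all[idx], s$values_mm[idx], xout = t_out, rule = 2)$y
  y <- zerophase_lowpass(y, target_fs_hz, cutoff_hz, order)
  # nearest original sample decides whether an output sample was observed
  near <- pmin(pmax(round((t_out - s$t0_ms) * s$fs_hz / 1000) + 1, 1), length(s))
  pupil_series(y, target_fs_hz, s$t0_ms, valid = s$valid[near])
}

#' Trial and session rejection by missing-data fraction
#'
#' Trials whose fraction of masked samples across baseline and modulation
#' phases exceeds `miss_threshold` (strict `>`) are excluded; the session is
#' flagged when the fraction of excluded trials exceeds `session_threshold`
#' (strict `>`). Masks must be the pre-interpolation masks.
#'
#' @param s a [pupil_series()] whose mask flags missing samples.
#' @param trials data frame with `trial`, `baseline_start_ms` and
#'   `modulation_end_ms` columns (e.g. a schedule).
#' @param miss_threshold default 0.30.
#' @param session_threshold default 0.50.
#' @return tibble with `trial`, `missing_frac`, `excluded`; attribute
#'   `session_excluded` carries the session flag.
#' @export
reject_trials <- function(s, trials, miss_threshold = 0.30,
                          session_threshold = 0.50) {
  stopifnot(inherits(s, "pupil_series"))
  miss <- vapply(seq_len(nrow(trials)), function(i) {
    idx <- ps_window_idx(s, trials$baseline_start_ms[i],
                         trials$modulation_end_ms[i])
    if (!length(idx)) return(NA_real_)
    mean(!s$valid[idx])
  }, numeric(1))
  excluded <- !is.na(miss) & miss > miss_threshold
  out <- tibble::tibble(trial = trials$trial, missing_frac = miss,
                        excluded = excluded)
  attr(out, "session_excluded") <- mean(excluded) > session_threshold
  out
}

#' Baseline-correct a trial
#'
#' The baseline is the mean over valid samples of the `window_ms`
#' (default 1000 ms) immediately preceding the modulation phase. Subtractive
#' mode subtracts it from every modulation sample; relative mode divides the
#' subtractive change by the baseline (used for evoked-dilation peaks).
#'
#' @param s a [pupil_series()] covering the trial.
#' @param modulation_start_ms,modulation_end_ms modulation phase (half-open).
#' @param window_ms baseline window length, default 1000.
#' @param mode `"subtractive"` or `"relative"`.
#' @return list with `trace` (corrected modulation-phase `pupil_series`),
#'   `baseline_mm`, and `flagged` (`TRUE` when the baseline window had no
#'   valid samples).
#' @export
baseline_correct <- function(s, modulation_start_ms, modulation_end_ms,
                             window_ms = 1000,
                             mode = c("subtractive", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "pupil_series"))
  b_idx <- ps_window_idx(s, modulation_start_ms - window_ms, modulation_start_ms)
  b_ok <- b_idx[s$valid[b_idx]]
  flagged <- length(b_ok) == 0
  baseline <- if (flagged) NA_real_ else mean(s$values_mm[b_ok])
  m_idx <- ps_window_idx(s, modulation_start_ms, modulation_end_ms)
  v <- s$values_mm[m_idx]
  corrected <- switch(mode,
    subtractive = v - baseline,
    relative = (v - baseline) / baseline
  )
  trace <- pupil_series(corrected, s$fs_hz,
                        t0_ms = ps_time_at(s, m_idx[1]),
                        valid = s$valid[m_idx])
  list(trace = trace, baseline_mm = baseline, flagged = flagged)
}

#' Run the full mask cascade and resample a binocular recording
#'
#' Applies the fixed pipeline order — range/blink validation (already in the
#' series masks), dilation-speed filter, trend-line filter, island removal,
#' binocular merge, resampling + smoothing — and returns both the merged
#' pre-resampling series (whose mask drives trial rejection) and the smooth
#' 1000 Hz series.
#'
#' @param left,right [pupil_series()] objects (range-validated on input, see
#'   [validate_sample()]).
#' @param mad_multiplier,passes,max_island_ms,min_gap_ms,target_fs_hz,cutoff_hz
#'   stage parameters; see the individual filters.
#' @return list with `merged` (native rate, cascade mask) and `smooth`
#'   (resampled series).
#' @export
preprocess_pupil <- function(left, right, mad_multiplier = 12, passes = 4,
                             max_island_ms = 50, min_gap_ms = 40,
                             target_fs_hz = 1000, cutoff_hz = 4) {
  clean1 <- function(s) {
    s <- dilation_speed_filter(s, mad_multiplier)
    s <- trendline_filter(s, passes, mad_multiplier, cutoff_hz)
    remove_islands(s, max_island_ms, min_gap_ms)
  }
  merged <- merge_eyes(clean1(left), clean1(right))
  list(merged = merged,
       smooth = resample_smooth(merged, target_fs_hz, cutoff_hz))
}
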