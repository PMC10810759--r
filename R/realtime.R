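#' @name realtime
#' @title Streaming quasi-real-time feedback engine
#'
#' @description
#' Per-sample validation, dilation-speed gating, two-sample display
#' smoothing, direction-gated ring geometry with exact annulus-area
#' conservation (isoluminant display), and post-trial feedback computation.
#' The engine is a pure fold over the input sample stream: replaying a
#' stream reproduces the frame log exactly.
NULL

#' Engine configuration
#'
#' Bundles the display and validation constants of the feedback engine.
#'
#' @param min_mm,max_mm physiological pupil-diameter validity bounds (mm).
#' @param velocity_threshold maximum plausible absolute dilation speed, in
#'   mm per ms (default 0.0027 mm/ms = 2.7 mm/s, consistent with peak
#'   pupillary light-reflex velocity).
#' @param gain_px_per_mm display gain mapping diameter change to ring-radius
#'   change. The default maps ±1 mm to ±50% of the baseline radius.
#' @param baseline_radius_px radius of the dashed baseline circle.
#' @param ring_thickness_px thickness of the ring at baseline radius; fixes
#'   the conserved annulus pixel area `2*pi*r0*t0`.
#' @param min_radius_px smallest radius ever displayed.
#' @param background_rgb background colour, default grey (150, 150, 150).
#' @param success_rgb,failure_rgb post-trial feedback colours.
#' @param isoluminance_tol tolerance (luminance units) for [is_isoluminant()].
#' @return a list of class `bf_engine_config`.
#' @export
engine_config <- function(min_mm = 1.5, max_mm = 9,
                          velocity_threshold = 0.0027,
                          gain_px_per_mm = NULL,
                          baseline_radius_px = 100,
                          ring_thickness_px = 5,
                          min_radius_px = 10,
                          background_rgb = c(150, 150, 150),
                          success_rgb = c(63, 176, 63),
                          failure_rgb = c(203, 118, 118),
                          isoluminance_tol = 0.5) {
  if (is.null(gain_px_per_mm)) gain_px_per_mm <- 0.5 * baseline_radius_px
  stopifnot(baseline_radius_px > 0, ring_thickness_px > 0, min_radius_px > 0)
  structure(list(
    min_mm = min_mm, max_mm = max_mm,
    velocity_threshold = velocity_threshold,
    gain_px_per_mm = gain_px_per_mm,
    baseline_radius_px = baseline_radius_px,
    area_px2 = 2 * pi * baseline_radius_px * ring_thickness_px,
    min_radius_px = min_radius_px,
    background_rgb = background_rgb,
    success_rgb = success_rgb, failure_rgb = failure_rgb,
    isoluminance_tol = isoluminance_tol
  ), class = "bf_engine_config")
}

#' Per-sample physiological validity
#'
#' A sample is invalid if it is the blink sentinel −1, missing, or outside
#' the plausible pupil-diameter range of 1.5–9 mm.
#'
#' @param diameter_mm numeric vector of raw diameters.
#' @param min_mm,max_mm validity bounds in mm.
#' @return logical vector, `TRUE` where valid.
#' @export
validate_sample <- function(diameter_mm, min_mm = 1.5, max_mm = 9) {
  is.finite(diameter_mm) & diameter_mm != -1 &
    diameter_mm >= min_mm & diameter_mm <= max_mm
}

#' Dilation-speed gate between consecutive accepted samples
#'
#' Rejects the current sample when the absolute diameter change per unit
#' time relative to the last accepted sample exceeds the plausibility
#' threshold.
#'
#' @param prev_t_ms,prev_mm time and diameter of the last accepted sample.
#' @param t_ms,mm time and diameter of the current sample.
#' @param threshold_mm_per_ms maximum plausible speed (default 0.0027).
#' @return `TRUE` if the current sample passes the gate.
#' @export
velocity_gate <- function(prev_t_ms, prev_mm, t_ms, mm,
                          threshold_mm_per_ms = 0.0027) {
  dt <- t_ms - prev_t_ms
  if (any(dt <= 0)) stop("stream ordering violated: non-positive time step",
                         call. = FALSE)
  abs(mm - prev_mm) / dt <= threshold_mm_per_ms
}

#' Smoothed display value from the acceptance buffer
#'
#' The displayed diameter is the mean of the last two accepted samples; with
#' a single accepted sample, that sample; with none, `NA` (hold previous
#' frame).
#'
#' @param buffer numeric vector of accepted samples in arrival order.
#' @return displayed diameter in mm, or `NA_real_` to signal a hold.
#' @export
display_value <- function(buffer) {
  n <- length(buffer)
  if (n == 0) return(NA_real_)
  mean(utils::tail(buffer, 2))
}

#' Direction-gated ring geometry
#'
#' Maps the displayed diameter to ring radius and thickness. The ring only
#' moves in the required direction: changes against the trial direction are
#' clamped to the baseline radius (`gated = TRUE`). Thickness is set to
#' `area / (2*pi*r)` so the number of coloured pixels on screen is constant.
#'
#' @param display_mm displayed (smoothed) diameter.
#' @param baseline_mm trial baseline diameter.
#' @param direction `"up"` or `"down"`.
#' @param config an [engine_config()].
#' @return a one-row tibble: `radius_px`, `thickness_px`, `gated`.
#' @export
feedback_geometry <- function(display_mm, baseline_mm,
                              direction = c("up", "down"),
                              config = engine_config()) {
  direction <- match.arg(direction)
  delta <- display_mm - baseline_mm
  signed <- if (direction == "up") delta else -delta
  gated <- signed < 0
  radius <- config$baseline_radius_px + config$gain_px_per_mm * max(signed, 0) *
    (if (direction == "up") 1 else -1)
  if (radius < config$min_radius_px) {
    radius <- config$min_radius_px
    gated <- TRUE
  }
  tibble::tibble(radius_px = radius,
                 thickness_px = config$area_px2 / (2 * pi * radius),
                 gated = gated)
}

#' Post-trial feedback summary
#'
#' Valid modulation-phase samples are averaged and compared with the trial
#' baseline; the mean change decides success (green) or failure (red) given
#' the required direction, and the extreme change (maximum for Up, minimum
#' for Down) is reported alongside.
#'
#' @param samples_mm modulation-phase samples (already validated; invalid
#'   samples may be passed as `NA`).
#' @param baseline_mm trial baseline diameter.
#' @param direction `"up"` or `"down"`.
#' @return a one-row tibble: `mean_change_mm`, `extreme_change_mm`,
#'   `success`, `colour`, `indeterminate`.
#' @export
post_trial_summary <- function(samples_mm, baseline_mm,
                               direction = c("up", "down")) {
  direction <- match.arg(direction)
  x <- samples_mm[is.finite(samples_mm)]
  if (length(x) == 0) {
    return(tibble::tibble(mean_change_mm = NA_real_,
                          extreme_change_mm = NA_real_,
                          success = NA, colour = NA_character_,
                          indeterminate = TRUE))
  }
  changes <- x - baseline_mm
  mean_change <- mean(changes)
  extreme <- if (direction == "up") max(changes) else min(changes)
  success <- if (direction == "up") mean_change > 0 else mean_change < 0
  tibble::tibble(mean_change_mm = mean_change, extreme_change_mm = extreme,
                 success = success,
                 colour = if (success) "green" else "red",
                 indeterminate = FALSE)
}

#' Relative luminance of an RGB triple
#'
#' `Y = 0.2126 R + 0.7152 G + 0.0722 B`, the sRGB linear-combination rule
#' used to keep all display colours isoluminant to the grey background.
#'
#' @param rgb numeric vector of length 3 (components on a common scale), or
#'   a 3-column matrix of colours.
#' @return relative luminance `Y` on the same scale.
#' @export
relative_luminance <- function(rgb) {
  w <- c(0.2126, 0.7152, 0.0722)
  if (is.matrix(rgb)) {
    stopifnot(ncol(rgb) == 3)
    return(drop(rgb %*% w))
  }
  stopifnot(length(rgb) == 3)
  sum(w * rgb)
}

#' @rdname relative_luminance
#' @param background_rgb reference colour (default grey 150).
#' @param tol luminance tolerance.
#' @export
is_isoluminant <- function(rgb, background_rgb = c(150, 150, 150), tol = 0.5) {
  abs(relative_luminance(rgb) - relative_luminance(background_rgb)) <= tol
}

#' Replay a sample stream through the feedback engine
#'
#' Deterministically folds a raw sample stream over one trial: baseline-phase
#' samples passing validation define the baseline mean (optionally only its
#' final portion), then each modulation-phase sample is validated, speed
#' gated, smoothed and mapped to ring geometry. Invalid samples produce hold
#' frames that repeat the previous geometry.
#'
#' @param stream data frame with columns `t_ms` and `mm` (raw diameters,
#'   blinks as −1), strictly increasing `t_ms`.
#' @param baseline_window,modulation_window numeric `c(start, end)` in ms,
#'   half-open.
#' @param direction `"up"` or `"down"`.
#' @param config an [engine_config()].
#' @param baseline_tail_ms if non-`NULL`, only the last this-many ms of the
#'   baseline window enter the baseline mean (the oddball paradigm uses the
#'   last 2000 ms of its shortened baseline).
#' @return list with `frames` (tibble: one row per modulation sample),
#'   `summary` (see [post_trial_summary()]) and `baseline_mm`.
#' @export
feedback_replay <- function(stream, baseline_window, modulation_window,
                            direction = c("up", "down"),
                            config = engine_config(),
                            baseline_tail_ms = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(c("t_ms", "mm") %in% names(stream)))
  if (any(diff(stream$t_ms) <= 0)) {
    stop("stream ordering violated: timestamps must be strictly increasing",
         call. = FALSE)
  }
  bw <- baseline_window
  if (!is.null(baseline_tail_ms)) bw[1] <- bw[2] - baseline_tail_ms
  in_b <- stream$t_ms >= bw[1] & stream$t_ms < bw[2]
  b_ok <- in_b & validate_sample(stream$mm, config$min_mm, config$max_mm)
  baseline_mm <- if (any(b_ok)) mean(stream$mm[b_ok]) else NA_real_

  in_m <- which(stream$t_ms >= modulation_window[1] &
                  stream$t_ms < modulation_window[2])
  n <- length(in_m)
  frames <- tibble::tibble(
    t_ms = stream$t_ms[in_m], raw_mm = stream$mm[in_m],
    accepted = FALSE, display_mm = NA_real_,
    radius_px = NA_real_, thickness_px = NA_real_,
    gated = NA, held = TRUE
  )
  buffer <- numeric(0)
  last_t <- NA_real_
  # before any accepted sample the display holds the baseline ring
  last_geom <- tibble::tibble(
    radius_px = config$baseline_radius_px,
    thickness_px = config$area_px2 / (2 * pi * config$baseline_radius_px),
    gated = FALSE
  )
  accepted_mm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mm <- frames$raw_mm[i]
    t <- frames$t_ms[i]
    ok <- !is.na(baseline_mm) &&
      validate_sample(mm, config$min_mm, config$max_mm)
    if (ok && length(buffer) > 0) {
      ok <- velocity_gate(last_t, buffer[length(buffer)], t, mm,
                          config$velocity_threshold)
    }
    if (ok) {
      buffer <- c(buffer, mm)
      last_t <- t
      accepted_mm[i] <- mm
      disp <- display_value(buffer)
      last_geom <- feedback_geometry(disp, baseline_mm, direction, config)
      frames$accepted[i] <- TRUE
      frames$display_mm[i] <- disp
      frames$held[i] <- FALSE
    }
    frames$radius_px[i] <- last_geom$radius_px
    frames$thickness_px[i] <- last_geom$thickness_px
    frames$gated[i] <- last_geom$gated
  }
  list(frames = frames,
       summary = post_trial_summary(accepted_mm, baseline_mm, direction),
       baseline_mm = baseline_mm)
}
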