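#' @name synth
#' @title Closed-loop synthetic pupillometry generator
#'
#' @description
#' Seeded generator emulating the statistical structure the analyses assume
#' — condition-dependent sustained pupil modulation with a logistic onset
#' ramp, baseline-dependent evoked dilations at tone onsets, slow 1/f
#' arousal noise, blinks coded as −1, binocular offset, condition-dependent
#' cardiac rate and variability, and reaction times coupled to pre-tone
#' baseline — so that every pipeline stage can be verified against known
#' ground truth.
NULL

#' Synthetic-session configuration
#'
#' All rates and amplitudes of the generator, with defaults chosen as a
#' verification test-bed: effect sizes in the range reported for trained
#' self-regulators, and noise levels kept below typical human recordings so
#' parameter-recovery checks isolate pipeline correctness (see the methods
#' vignette for the rationale).
#'
#' @param n_participants cohort size used by recovery studies, default 20.
#' @param fs_hz raw sampling rate (60 for training rigs, 1000 in-scanner).
#' @param baseline_mean_mm,baseline_sd_mm between-participant baseline
#'   diameter distribution.
#' @param up_effect_mm,down_effect_mm asymptotic condition effects (mm).
#' @param learning_rate_per_session fraction of the asymptotic effect added
#'   per completed training session (`session_scale = min(1, learning_rate *
#'   n_sessions_done)` multiplies both effects); default 1/3.
#' @param ramp_half_ms,ramp_tau_ms logistic onset-ramp midpoint and time
#'   constant of the condition effect within the modulation phase.
#' @param decay_tau_ms exponential return-to-baseline time constant after
#'   the modulation phase.
#' @param blink_rate_per_min blink rate, blinks coded −1 in both eyes.
#' @param blink_duration_ms_range uniform blink-duration range.
#' @param noise_sd_mm standard deviation of the slow common 1/f arousal
#'   noise.
#' @param noise_band_hz frequency band of the 1/f noise.
#' @param measurement_noise_sd_mm white per-eye sensor noise.
#' @param evoked_amplitude_mm evoked-dilation amplitude at the reference
#'   (configured mean) baseline.
#' @param baseline_dependence_exponent target `beta_x`: evoked peaks scale
#'   as `baseline^beta_x`, i.e. relative peaks as `baseline^(beta_x - 1)`.
#' @param evoked_lognoise_sd log-normal amplitude noise.
#' @param evoked_peak_ms,evoked_shape gamma-kernel mode and shape (the
#'   dilation peaks ~0.8 s post-tone and has returned to baseline by ~2 s).
#' @param rt_base_ms,rt_pupil_slope_ms_per_mm,rt_noise_sd_ms reaction-time
#'   model: base + slope x (pre-tone baseline − configured mean) + noise.
#' @param time_on_task_rt_ms_per_trial,time_on_task_pupil_mm_per_trial
#'   linear time-on-task drifts.
#' @param hit_rate,false_alarm_rate response probabilities to targets and
#'   standards.
#' @param hr_base_bpm,hr_up_minus_down_bpm,rr_variability_ms cardiac model:
#'   R-R intervals Gaussian around 60000 / HR(condition).
#' @param eye_offset_mm fixed right-minus-left diameter offset.
#' @param eye_noise_sd_mm (deprecated alias of `measurement_noise_sd_mm`,
#'   ignored when `NULL`).
#' @param seed mandatory integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 20, fs_hz = 60,
                         baseline_mean_mm = 4.5, baseline_sd_mm = 0.5,
                         up_effect_mm = 0.4, down_effect_mm = -0.4,
                         learning_rate_per_session = 1 / 3,
                         ramp_half_ms = 1000, ramp_tau_ms = 300,
                         decay_tau_ms = 1000,
                         blink_rate_per_min = 15,
                         blink_duration_ms_range = c(100, 400),
                         noise_sd_mm = 0.04,
                         noise_band_hz = c(0.002, 0.05),
                         measurement_noise_sd_mm = 0.008,
                         evoked_amplitude_mm = 0.6,
                         baseline_dependence_exponent = 0.8,
                         evoked_lognoise_sd = 0.05,
                         evoked_peak_ms = 800, evoked_shape = 8,
                         rt_base_ms = 450, rt_pupil_slope_ms_per_mm = 30,
                         rt_noise_sd_ms = 40,
                         time_on_task_rt_ms_per_trial = 0.2,
                         time_on_task_pupil_mm_per_trial = -5e-4,
                         hit_rate = 0.95, false_alarm_rate = 0.01,
                         hr_base_bpm = 70, hr_up_minus_down_bpm = 5,
                         rr_variability_ms = 30,
                         eye_offset_mm = 0.15, eye_noise_sd_mm = NULL,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!is.null(eye_noise_sd_mm)) measurement_noise_sd_mm <- eye_noise_sd_mm
  cfg <- list(
    n_participants = n_participants, fs_hz = fs_hz,
    baseline_mean_mm = baseline_mean_mm, baseline_sd_mm = baseline_sd_mm,
    up_effect_mm = up_effect_mm, down_effect_mm = down_effect_mm,
    learning_rate_per_session = learning_rate_per_session,
    ramp_half_ms = ramp_half_ms, ramp_tau_ms = ramp_tau_ms,
    decay_tau_ms = decay_tau_ms,
    blink_rate_per_min = blink_rate_per_min,
    blink_duration_ms_range = blink_duration_ms_range,
    noise_sd_mm = noise_sd_mm, noise_band_hz = noise_band_hz,
    measurement_noise_sd_mm = measurement_noise_sd_mm,
    evoked_amplitude_mm = evoked_amplitude_mm,
    baseline_dependence_exponent = baseline_dependence_exponent,
    evoked_lognoise_sd = evoked_lognoise_sd,
    evoked_peak_ms = evoked_peak_ms, evoked_shape = evoked_shape,
    rt_base_ms = rt_base_ms,
    rt_pupil_slope_ms_per_mm = rt_pupil_slope_ms_per_mm,
    rt_noise_sd_ms = rt_noise_sd_ms,
    time_on_task_rt_ms_per_trial = time_on_task_rt_ms_per_trial,
    time_on_task_pupil_mm_per_trial = time_on_task_pupil_mm_per_trial,
    hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
    hr_base_bpm = hr_base_bpm, hr_up_minus_down_bpm = hr_up_minus_down_bpm,
    rr_variability_ms = rr_variability_ms,
    eye_offset_mm = eye_offset_mm, seed = seed
  )
  lo <- baseline_mean_mm - 3 * baseline_sd_mm + min(0, down_effect_mm) -
    3 * noise_sd_mm
  hi <- baseline_mean_mm + 3 * baseline_sd_mm + max(0, up_effect_mm) +
    evoked_amplitude_mm + 3 * noise_sd_mm
  if (lo < 1.5 || hi > 9) {
    stop("infeasible config: diameters would leave the physiological ",
         "range of 1.5-9 mm", call. = FALSE)
  }
  if (blink_rate_per_min < 0 || noise_sd_mm < 0 || measurement_noise_sd_mm < 0) {
    stop("rates and noise levels must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Band-limited 1/f (pink) noise scaled to the requested sd.
pink_noise <- function(n, fs_hz, sd_mm, band_hz) {
  if (sd_mm <= 0 || n < 4) return(numeric(n))
  f <- seq(0, fs_hz / 2, length.out = floor(n / 2) + 1)
  amp <- rep(0, length(f))
  sel <- f >= band_hz[1] & f <= band_hz[2] & f > 0
  if (!any(sel)) return(numeric(n))
  amp[sel] <- 1 / sqrt(f[sel])
  phase <- runif(length(f), 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(length(spec) - (n %% 2 == 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_mm
}

# Gamma-shaped evoked dilation kernel, unit peak at `peak_ms`.
evoked_kernel <- function(t_ms, peak_ms, shape) {
  u <- pmax(t_ms, 0) / peak_ms
  ifelse(t_ms < 0, 0, u^shape * exp(shape * (1 - u)))
}

# Logistic condition ramp within [0, dur); 0 before onset.
condition_ramp <- function(rel_ms, half_ms, tau_ms) {
  ifelse(rel_ms < 0, 0, 1 / (1 + exp(-(rel_ms - half_ms) / tau_ms)))
}

#' Simulate one synthetic recording session
#'
#' Generates a raw binocular sample stream (blinks as −1), an R-peak list,
#' response events and a ground-truth record for a single participant
#' following a schedule from the paradigm builders. The latent pupil signal
#' is baseline + condition ramp + 1/f arousal noise + evoked responses
#' (amplitude proportional to the momentary baseline raised to the
#' configured exponent) + linear time-on-task drift; all draws come from the
#' seeded generator.
#'
#' @param cfg a [synth_config()].
#' @param schedule a `bf_schedule`.
#' @param sessions_done completed training sessions (scales the condition
#'   effects through the learning rate); default effects at asymptote.
#' @return list of class `synth_session`: `samples` (tibble `t_ms`,
#'   `left_mm`, `right_mm`), `peaks_ms`, `responses`, `truth`, `schedule`,
#'   `cfg`.
#' @export
simulate_session <- function(cfg, schedule, sessions_done = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(schedule, "bf_schedule"))
  scale <- if (is.null(sessions_done)) 1 else {
    min(1, cfg$learning_rate_per_session * sessions_done)
  }
  eff <- c(up = cfg$up_effect_mm * scale, down = cfg$down_effect_mm * scale,
           control = 0)
  tones <- attr(schedule, "tones")
  with_seed(cfg$seed, {
    baseline <- min(max(rnorm(1, cfg$baseline_mean_mm, cfg$baseline_sd_mm),
                        1.8), 8.2)
    end_ms <- max(schedule$trial_end_ms)
    dt <- 1000 / cfg$fs_hz
    n <- ceiling(end_ms / dt)
    t <- (seq_len(n) - 1) * dt

    # condition effect with logistic onset and exponential offset decay
    cond_sig <- numeric(n)
    mean_dur <- mean(schedule$trial_end_ms - schedule$trial_start_ms)
    drift <- cfg$time_on_task_pupil_mm_per_trial * t / mean_dur
    for (i in seq_len(nrow(schedule))) {
      e <- eff[[schedule$condition[i]]]
      if (e == 0) next
      m0 <- schedule$modulation_start_ms[i]
      m1 <- schedule$modulation_end_ms[i]
      idx <- which(t >= m0 & t < m1)
      cond_sig[idx] <- cond_sig[idx] +
        e * condition_ramp(t[idx] - m0, cfg$ramp_half_ms, cfg$ramp_tau_ms)
      at_end <- e * condition_ramp(m1 - m0, cfg$ramp_half_ms, cfg$ramp_tau_ms)
      idx2 <- which(t >= m1 & t < m1 + 6 * cfg$decay_tau_ms)
      cond_sig[idx2] <- cond_sig[idx2] +
        at_end * exp(-(t[idx2] - m1) / cfg$decay_tau_ms)
    }
    slow <- pink_noise(n, cfg$fs_hz, cfg$noise_sd_mm, cfg$noise_band_hz)
    latent <- baseline + cond_sig + slow + drift

    # evoked responses at tone onsets, amplitude ~ baseline^beta
    tone_truth <- NULL
    if (!is.null(tones)) {
      beta <- cfg$baseline_dependence_exponent
      k_len <- ceiling(5 * cfg$evoked_peak_ms / dt)
      x_pre <- amp <- numeric(nrow(tones))
      for (j in seq_len(nrow(tones))) {
        i0 <- floor(tones$onset_ms[j] / dt) + 1
        x_pre[j] <- latent[min(i0, n)]
        amp[j] <- cfg$evoked_amplitude_mm *
          (x_pre[j] / cfg$baseline_mean_mm)^beta *
          exp(rnorm(1, 0, cfg$evoked_lognoise_sd))
        idx <- i0:min(i0 + k_len, n)
        latent[idx] <- latent[idx] +
          amp[j] * evoked_kernel(t[idx] - tones$onset_ms[j],
                                 cfg$evoked_peak_ms, cfg$evoked_shape)
      }
      tone_truth <- tibble::tibble(trial = tones$trial, tone = tones$tone,
                                   kind = tones$kind, onset_ms = tones$onset_ms,
                                   x_pre_mm = x_pre, amplitude_mm = amp)
    }

    left <- latent - cfg$eye_offset_mm / 2 +
      rnorm(n, 0, cfg$measurement_noise_sd_mm)
    right <- latent + cfg$eye_offset_mm / 2 +
      rnorm(n, 0, cfg$measurement_noise_sd_mm)

    # blinks: -1 spans in both eyes
    n_blinks <- rpois(1, cfg$blink_rate_per_min * end_ms / 60000)
    if (n_blinks > 0) {
      b_on <- runif(n_blinks, 0, end_ms)
      b_dur <- runif(n_blinks, cfg$blink_duration_ms_range[1],
                     cfg$blink_duration_ms_range[2])
      for (b in seq_len(n_blinks)) {
        idx <- which(t >= b_on[b] & t < b_on[b] + b_dur[b])
        left[idx] <- -1
        right[idx] <- -1
      }
    }

    # cardiac: sequential R-R intervals, condition-dependent rate
    in_mod <- function(time) {
      i <- which(schedule$modulation_start_ms <= time &
                   time < schedule$modulation_end_ms)
      if (length(i)) schedule$condition[i[1]] else NA_character_
    }
    peaks <- numeric(0)
    tp <- runif(1, 0, 1000)
    while (tp < end_ms) {
      peaks <- c(peaks, tp)
      cond <- in_mod(tp)
      hr <- cfg$hr_base_bpm +
        if (is.na(cond)) 0 else switch(cond,
          up = cfg$hr_up_minus_down_bpm / 2,
          down = -cfg$hr_up_minus_down_bpm / 2, 0)
      tp <- tp + max(rnorm(1, 60000 / hr, cfg$rr_variability_ms), 300)
    }

    # behavioural responses to tones
    responses <- NULL
    if (!is.null(tones)) {
      n_tone <- nrow(tones)
      p_resp <- ifelse(tones$kind == "target", cfg$hit_rate,
                       cfg$false_alarm_rate)
      responded <- runif(n_tone) < p_resp
      rt <- cfg$rt_base_ms +
        cfg$rt_pupil_slope_ms_per_mm * (tone_truth$x_pre_mm - cfg$baseline_mean_mm) +
        cfg$time_on_task_rt_ms_per_trial * (tones$trial - 1) +
        rnorm(n_tone, 0, cfg$rt_noise_sd_ms)
      responses <- tibble::tibble(
        trial = tones$trial, tone = tones$tone, kind = tones$kind,
        onset_ms = tones$onset_ms, responded = responded,
        rt_ms = ifelse(responded, pmax(rt, 150), NA_real_)
      )
    }

    mod_dur <- schedule$modulation_end_ms[1] - schedule$modulation_start_ms[1]
    r_grid <- condition_ramp(seq(0, mod_dur - 1), cfg$ramp_half_ms,
                             cfg$ramp_tau_ms)
    truth <- list(
      baseline_mm = baseline,
      up_effect_mm = eff[["up"]], down_effect_mm = eff[["down"]],
      expected_modulation_index_mm = (eff[["up"]] - eff[["down"]]) * mean(r_grid),
      beta_x = cfg$baseline_dependence_exponent,
      hr_up_minus_down_bpm = cfg$hr_up_minus_down_bpm,
      tones = tone_truth
    )
    structure(list(
      samples = tibble::tibble(t_ms = t, left_mm = left, right_mm = right),
      peaks_ms = peaks, responses = responses, truth = truth,
      schedule = schedule, cfg = cfg
    ), class = "synth_session")
  })
}

#' @export
#' @method print synth_session
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> %d samples @ %g Hz, %d trials, %d R peaks (seed %s)\n",
    nrow(x$samples), x$cfg$fs_hz, nrow(x$schedule), length(x$peaks_ms),
    format(x$cfg$seed)))
  invisible(x)
}

#' Stream a synthetic session through the feedback engine
#'
#' Replays every feedback-carrying trial of a simulated session through
#' [feedback_replay()] and collects frame logs and post-trial summaries for
#' end-to-end tests.
#'
#' @param cfg a [synth_config()].
#' @param schedule a `bf_schedule` with feedback trials.
#' @param engine an [engine_config()].
#' @return list with `session`, `frames` (list per trial) and `summaries`
#'   (one row per trial).
#' @export
simulate_closed_loop <- function(cfg, schedule, engine = engine_config()) {
  sim <- simulate_session(cfg, schedule)
  stream <- data.frame(t_ms = sim$samples$t_ms, mm = sim$samples$left_mm)
  fb <- schedule[schedule$feedback_mode %in% c("online", "yoked") &
                   schedule$condition %in% c("up", "down"), ]
  frames <- vector("list", nrow(fb))
  sums <- vector("list", nrow(fb))
  for (i in seq_len(nrow(fb))) {
    r <- fb[i, ]
    res <- feedback_replay(
      stream,
      baseline_window = c(r$baseline_start_ms, r$modulation_start_ms),
      modulation_window = c(r$modulation_start_ms, r$modulation_end_ms),
      direction = r$condition, config = engine
    )
    frames[[i]] <- res$frames
    sums[[i]] <- cbind(tibble::tibble(trial = r$trial, condition = r$condition,
                                      baseline_mm = res$baseline_mm),
                       res$summary)
  }
  list(session = sim, frames = frames,
       summaries = if (length(sums)) do.call(rbind, sums) else NULL)
}
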