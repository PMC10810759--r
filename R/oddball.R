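#' @name oddball_analysis
#' @title Tone-locked evoked-response and behavioural analysis
#'
#' @description
#' Epoching of tone-locked pupil segments with pre-tone baseline
#' normalization, the log-log baseline-bias test of evoked peaks, the
#' repeated-measures correlation, time-on-task detrending, and behavioural
#' summaries for the oddball task.
NULL

#' Extract tone-locked epochs
#'
#' Cuts a 3.5 s epoch around each tone from −0.5 to +3 s (half-open at the
#' right edge: 3500 samples at 1000 Hz), subtracts the pre-tone baseline —
#' the mean of the `baseline_ms` (default 500 ms) of data preceding tone
#' onset — and records the peak: the maximal baseline-corrected dilation in
#' the post-onset search window. Epochs that overlap the series edges are
#' dropped with a warning; epochs whose baseline window holds no valid
#' sample are flagged.
#'
#' @param s a [pupil_series()] (typically the smoothed 1000 Hz series).
#' @param onsets_ms tone onsets in ms.
#' @param kinds optional character vector of tone kinds, recycled onto the
#'   kept epochs.
#' @param window_ms epoch window `c(start, end)` relative to onset, half-open;
#'   default `c(-500, 3000)`.
#' @param baseline_ms pre-tone baseline length, default 500.
#' @param peak_window_ms search window for the peak (open interval), default
#'   `c(0, 3000)`.
#' @return tibble with one row per kept epoch: `onset_ms`, `kind`,
#'   `baseline_mm`, `peak_mm`, `flagged`, and a list-column `trace` of
#'   corrected traces.
#' @export
epoch_tones <- function(s, onsets_ms, kinds = NULL,
                        window_ms = c(-500, 3000), baseline_ms = 500,
                        peak_window_ms = c(0, 3000)) {
  stopifnot(inherits(s, "pupil_series"))
  dt <- 1000 / s$fs_hz
  t_end <- s$t0_ms + length(s) * dt
  keep <- onsets_ms + window_ms[1] >= s$t0_ms & onsets_ms + window_ms[2] <= t_end
  if (any(!keep)) {
    warning(sprintf("%d epoch(s) overlapping the series edges dropped",
                    sum(!keep)))
  }
  onsets <- onsets_ms[keep]
  if (!is.null(kinds)) kinds <- kinds[keep]
  rows <- lapply(seq_along(onsets), function(i) {
    on <- onsets[i]
    b_idx <- ps_window_idx(s, on - baseline_ms, on)
    b_ok <- b_idx[s$valid[b_idx]]
    flagged <- length(b_ok) == 0
    baseline <- if (flagged) NA_real_ else mean(s$values_mm[b_ok])
    e_idx <- ps_window_idx(s, on + window_ms[1], on + window_ms[2])
    trace <- s$values_mm[e_idx] - baseline
    rel_t <- ps_time_at(s, e_idx) - on
    p_idx <- rel_t > peak_window_ms[1] & rel_t < peak_window_ms[2]
    peak <- if (flagged) NA_real_ else max(trace[p_idx])
    tibble::tibble(onset_ms = on,
                   kind = if (is.null(kinds)) NA_character_ else kinds[i],
                   baseline_mm = baseline, peak_mm = peak, flagged = flagged,
                   trace = list(trace))
  })
  if (!length(rows)) {
    return(tibble::tibble(onset_ms = numeric(), kind = character(),
                          baseline_mm = numeric(), peak_mm = numeric(),
                          flagged = logical(), trace = list()))
  }
  do.call(rbind, rows)
}

#' Baseline-bias test for evoked-dilation peaks
#'
#' Correlating a relative change `y/x` with `x` itself is biased, but the
#' exponent of the power-law relation can be estimated without bias from the
#' per-participant regression `lm(log(y) ~ log(x))` with `y` the evoked
#' dilation peak and `x` the pre-tone baseline diameter: under
#' `y/x = x^(beta_x - 1) * exp(intercept) * exp(eps)` the slope is `beta_x`,
#' and `beta_x - 1 = 0` means the baseline has no influence on the relative
#' peak. The group-level test is a one-sample t-test of the per-participant
#' slopes against 1.
#'
#' @param baselines,peaks strictly positive numeric vectors (non-positive
#'   pairs are excluded and counted).
#' @param participant_ids vector of participant labels.
#' @return list of class `baseline_bias`: `beta_x` (named per participant),
#'   `intercepts`, `t_stat`, `df`, `p_value`, `n_excluded`,
#'   `group_test_available`.
#' @export
baseline_bias_test <- function(baselines, peaks, participant_ids) {
  stopifnot(length(baselines) == length(peaks),
            length(baselines) == length(participant_ids))
  ok <- is.finite(baselines) & is.finite(peaks) & baselines > 0 & peaks > 0
  n_excluded <- sum(!ok)
  x <- baselines[ok]; y <- peaks[ok]; id <- as.character(participant_ids[ok])
  fits <- lapply(split(seq_along(x), id), function(i) {
    if (length(i) < 2 || length(unique(x[i])) < 2) return(NULL)
    coef(lm(log(y[i]) ~ log(x[i])))
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("no participant with enough usable trials",
                          call. = FALSE)
  beta <- vapply(fits, `[[`, numeric(1), 2L)
  intercepts <- vapply(fits, `[[`, numeric(1), 1L)
  if (length(beta) >= 2) {
    m <- mean(beta); sdev <- sd(beta); k <- length(beta)
    if (sdev < 1e-10 * max(1, abs(m))) {
      # degenerate: (near-)identical slopes across participants
      t_stat <- if (abs(m - 1) < 1e-10) 0 else Inf * sign(m - 1)
      res <- list(t_stat = t_stat, df = k - 1,
                  p_value = if (t_stat == 0) 1 else 0,
                  group_test_available = TRUE)
    } else {
      t_stat <- (m - 1) / (sdev / sqrt(k))
      res <- list(t_stat = t_stat, df = k - 1,
                  p_value = 2 * pt(-abs(t_stat), k - 1),
                  group_test_available = TRUE)
    }
  } else {
    res <- list(t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                group_test_available = FALSE)
  }
  structure(c(list(beta_x = beta, intercepts = intercepts,
                   n_excluded = n_excluded), res),
            class = "baseline_bias")
}

#' @export
#' @method print baseline_bias
print.baseline_bias <- function(x, ...) {
  cat(sprintf(
    "Baseline-bias test: mean beta_x = %.4f (n = %d participants)\n",
    mean(x$beta_x), length(x$beta_x)))
  if (x$group_test_available) {
    cat(sprintf("  H0 beta_x - 1 = 0: t(%g) = %.3f, p = %.4g\n",
                x$df, x$t_stat, x$p_value))
  } else {
    cat("  group test unavailable (single participant)\n")
  }
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Common within-participant correlation between two repeatedly measured
#' variables, estimated with the shared-slope analysis-of-covariance
#' formulation: participant-specific intercepts, one common slope. The
#' coefficient's sign matches the common slope and the degrees of freedom
#' are `N - k - 1` for `k` participants.
#'
#' @param x,y numeric vectors of paired within-participant measures.
#' @param participant_ids participant labels (at least 2 participants with
#'   at least 2 trials each).
#' @return list with `r_rm`, `df`, `p_value`, `slope`.
#' @export
rm_correlation <- function(x, y, participant_ids) {
  stopifnot(length(x) == length(y), length(x) == length(participant_ids))
  id <- factor(participant_ids)
  if (nlevels(id) < 2) stop("need at least 2 participants", call. = FALSE)
  if (any(tabulate(id) < 2)) stop("every participant needs at least 2 trials",
                                  call. = FALSE)
  wv <- tapply(x, id, var)
  if (any(wv == 0)) stop("zero within-participant variance in x", call. = FALSE)
  fit <- lm(y ~ id + x)
  a <- anova(fit)
  ss_x <- a["x", "Sum Sq"]
  ss_err <- a["Residuals", "Sum Sq"]
  slope <- coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df <- length(x) - nlevels(id) - 1
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r_rm = r, df = df, p_value = 2 * pt(-abs(tstat), df), slope = slope)
}

#' Time-on-task screening and detrending
#'
#' Screens for a linear time-on-task trend with a mixed model — a fixed
#' slope on the trial index plus a random intercept per participant (REML;
#' a fixed-effects fit with participant dummies is used as fallback when the
#' mixed fit is degenerate). When the slope is significant at `alpha`, a
#' per-participant least-squares linear detrend is applied: the fitted line
#' is removed and the participant mean retained. Participants with fewer
#' than 3 trials are skipped.
#'
#' @param values numeric vector (e.g. reaction times or baseline diameters).
#' @param trial_index trial number in ascending experiment order.
#' @param participant_ids participant labels.
#' @param alpha two-tailed significance threshold for applying the detrend,
#'   default 0.05.
#' @return list with `values` (detrended when the trend was significant),
#'   `slope`, `p_value`, `applied`, `skipped` (participants with <3 trials).
#' @export
detrend_time_on_task <- function(values, trial_index, participant_ids,
                                 alpha = 0.05) {
  stopifnot(length(values) == length(trial_index),
            length(values) == length(participant_ids))
  id <- factor(participant_ids)
  d <- data.frame(y = values, tot = trial_index, id = id)
  scr <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ tot + (1 | id), data = d)
    ))
    cf <- coef(summary(fit))
    list(slope = cf["tot", "Estimate"], p = cf["tot", "Pr(>|t|)"])
  }, error = function(e) NULL)
  if (is.null(scr) || !is.finite(scr$p)) {
    fit <- lm(y ~ tot + id, data = d)
    cf <- coef(summary(fit))
    scr <- if ("tot" %in% rownames(cf)) {
      p <- cf["tot", "Pr(>|t|)"]
      # noise-free exact fits have no residual error; a non-zero slope is then a trend
      if (!is.finite(p)) p <- if (abs(cf["tot", "Estimate"]) > 1e-8) 0 else 1
      list(slope = cf["tot", "Estimate"], p = p)
    } else {
      list(slope = 0, p = 1)
    }
  }
  applied <- is.finite(scr$p) && scr$p < alpha && scr$slope != 0
  out <- values
  skipped <- character(0)
  if (applied) {
    for (g in levels(id)) {
      i <- which(id == g)
      if (length(i) < 3) {
        skipped <- c(skipped, g)
        next
      }
      f <- lm(values[i] ~ trial_index[i])
      out[i] <- stats::residuals(f) + mean(values[i])
    }
  }
  list(values = out, slope = scr$slope, p_value = scr$p, applied = applied,
       skipped = skipped)
}

#' Behavioural summary of oddball responses
#'
#' Computes hit and false-alarm percentages, accuracy (their difference) and
#' reaction-time statistics for one participant. False alarms never enter
#' the RT statistics, and RTs farther than `rt_sd_multiplier` standard
#' deviations from the participant's mean are excluded.
#'
#' @param responses data frame with columns `kind` (`"standard"`/`"target"`),
#'   `responded` (logical) and `rt_ms` (`NA` when no press).
#' @param rt_sd_multiplier default 2.
#' @return one-row tibble: `n_targets`, `n_standards`, `hit_pct`,
#'   `false_alarm_pct`, `accuracy_pct`, `mean_rt_ms`, `sd_rt_ms`,
#'   `n_rt_excluded`, `accuracy_defined`.
#' @export
behavioural_summary <- function(responses, rt_sd_multiplier = 2) {
  stopifnot(all(c("kind", "responded", "rt_ms") %in% names(responses)))
  tg <- responses$kind == "target"
  st <- responses$kind == "standard"
  n_t <- sum(tg); n_s <- sum(st)
  hit_pct <- if (n_t > 0) 100 * sum(responses$responded[tg]) / n_t else NA_real_
  fa_pct <- if (n_s > 0) 100 * sum(responses$responded[st]) / n_s else 0
  accuracy <- if (n_t > 0) hit_pct - fa_pct else NA_real_
  rts <- responses$rt_ms[tg & responses$responded]
  rts <- rts[is.finite(rts)]
  n_excl <- 0L
  if (length(rts) >= 2) {
    m <- mean(rts); sdev <- sd(rts)
    keep <- rts >= m - rt_sd_multiplier * sdev & rts <= m + rt_sd_multiplier * sdev
    n_excl <- sum(!keep)
    rts <- rts[keep]
  }
  tibble::tibble(
    n_targets = n_t, n_standards = n_s,
    hit_pct = hit_pct, false_alarm_pct = fa_pct, accuracy_pct = accuracy,
    mean_rt_ms = if (length(rts)) mean(rts) else NA_real_,
    sd_rt_ms = if (length(rts) > 1) sd(rts) else NA_real_,
    n_rt_excluded = n_excl,
    accuracy_defined = n_t > 0
  )
}
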