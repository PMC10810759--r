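# Brute-force, loop-based reimplementations of the preprocessing filters.
# These recompute every mask decision sample by sample and are kept
# deliberately naive so the vectorized filters can be checked against them
# exactly on small fixtures.

oracle_speed_mask <- function(t, v, valid, mult = 12) {
  idx <- which(valid)
  k <- length(idx)
  if (k < 3) return(valid)
  sp <- numeric(k)
  for (j in seq_len(k)) {
    cands <- c()
    if (j > 1) {
      cands <- c(cands, abs(v[idx[j]] - v[idx[j - 1]]) / (t[idx[j]] - t[idx[j - 1]]))
    }
    if (j < k) {
      cands <- c(cands, abs(v[idx[j + 1]] - v[idx[j]]) / (t[idx[j + 1]] - t[idx[j]]))
    }
    sp[j] <- max(cands)
  }
  med <- median(sp)
  madv <- median(abs(sp - med))
  thr <- med + mult * madv
  if (thr < 0.001) thr <- 0.001      # same numerical floor as the filter
  out <- valid
  for (j in seq_len(k)) {
    if (sp[j] > thr) out[idx[j]] <- FALSE
  }
  out
}

oracle_trend_mask <- function(t, v, valid, fs, passes = 4, mult = 12,
                              cutoff = 4) {
  out <- valid
  for (p in seq_len(passes)) {
    idx <- which(out)
    if (length(idx) <= 2) next
    interp <- approx(t[idx], v[idx], xout = t, rule = 2)$y
    trend <- pupilbf::zerophase_lowpass(interp, fs, cutoff)
    dev <- numeric(length(idx))
    for (j in seq_along(idx)) dev[j] <- abs(v[idx[j]] - trend[idx[j]])
    med <- median(dev)
    madv <- median(abs(dev - med))
    thr <- med + mult * madv
    if (thr < 0.01) thr <- 0.01      # same numerical floor as the filter
    for (j in seq_along(idx)) {
      if (dev[j] > thr) out[idx[j]] <- FALSE
    }
  }
  out
}

oracle_island_mask <- function(valid, fs, max_island_ms = 50, min_gap_ms = 40) {
  n <- length(valid)
  dt <- 1000 / fs
  out <- valid
  i <- 1
  while (i <= n) {
    if (!valid[i]) { i <- i + 1; next }
    j <- i
    while (j < n && valid[j + 1]) j <- j + 1
    run_w <- (j - i + 1) * dt
    # preceding gap
    gl <- 0; k <- i - 1
    while (k >= 1 && !valid[k]) { gl <- gl + 1; k <- k - 1 }
    left_w <- if (i == 1) Inf else gl * dt
    gr <- 0; k <- j + 1
    while (k <= n && !valid[k]) { gr <- gr + 1; k <- k + 1 }
    right_w <- if (j == n) Inf else gr * dt
    if (run_w <= max_island_ms && left_w > min_gap_ms && right_w > min_gap_ms) {
      out[i:j] <- FALSE
    }
    i <- j + 1
  }
  out
}

oracle_merge_values <- function(lv, lok, rv, rok) {
  both <- lok & rok
  offset <- if (any(both)) mean(rv[both] - lv[both]) else 0
  n <- length(lv)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (lok[i] && rok[i]) out[i] <- (lv[i] + rv[i]) / 2
    else if (lok[i]) out[i] <- lv[i] + offset / 2
    else if (rok[i]) out[i] <- rv[i] - offset / 2
  }
  out
}

# Random small fixture: smooth base signal with injected spikes and gaps.
make_fixture <- function(seed, n = 180, fs = 60) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * 1000 / fs
  v <- 4 + 0.4 * sin(2 * pi * t / 4000) + rnorm(n, 0, 0.02)
  n_spike <- sample(1:4, 1)
  v[sample(n, n_spike)] <- v[sample(n, n_spike)] + runif(n_spike, 0.5, 1.5)
  valid <- rep(TRUE, n)
  n_gap <- sample(1:3, 1)
  for (g in seq_len(n_gap)) {
    at <- sample(n - 6, 1)
    valid[at:(at + sample(2:6, 1))] <- FALSE
  }
  list(t = t, v = v, valid = valid, fs = fs,
       series = pupilbf::pupil_series(v, fs, valid = valid))
}

# Shared synthetic-recovery helpers -------------------------------------

# Pipeline estimate of the modulation index and modulation-phase heart rates
# for one simulated training session.
recover_training_session <- function(cfg, sched) {
  sim <- simulate_session(cfg, sched)
  L <- samples_to_series(sim$samples, "left")
  R <- samples_to_series(sim$samples, "right")
  L$valid <- L$valid & validate_sample(L$values_mm)
  R$valid <- R$valid & validate_sample(R$values_mm)
  pp <- preprocess_pupil(L, R)
  up <- dn <- NULL
  for (i in seq_len(nrow(sched))) {
    bc <- baseline_correct(pp$smooth, sched$modulation_start_ms[i],
                           sched$modulation_end_ms[i])
    if (sched$condition[i] == "up") up <- rbind(up, bc$trace$values_mm)
    else dn <- rbind(dn, bc$trace$values_mm)
  }
  hr_by <- vapply(c("up", "down"), function(cc) {
    rows <- sched[sched$condition == cc, ]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      heart_rate(rr_in_window(sim$peaks_ms,
                              c(rows$modulation_start_ms[i],
                                rows$modulation_end_ms[i])))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(index = modulation_index(colMeans(up), colMeans(dn))$value_mm,
       truth_index = sim$truth$expected_modulation_index_mm,
       hr_diff = hr_by[["up"]] - hr_by[["down"]],
       truth_hr_diff = sim$truth$hr_up_minus_down_bpm)
}

# Pipeline estimate of the log-log baseline exponent for one oddball session.
recover_oddball_beta <- function(cfg, sched) {
  sim <- simulate_session(cfg, sched)
  L <- samples_to_series(sim$samples, "left")
  R <- samples_to_series(sim$samples, "right")
  L$valid <- L$valid & validate_sample(L$values_mm)
  R$valid <- R$valid & validate_sample(R$values_mm)
  pp <- preprocess_pupil(L, R)
  tn <- schedule_tones(sched)
  ep <- suppressWarnings(epoch_tones(pp$smooth, tn$onset_ms, tn$kind))
  ok <- !ep$flagged & is.finite(ep$peak_mm) & ep$peak_mm > 0 & ep$baseline_mm > 0
  unname(coef(lm(log(ep$peak_mm[ok]) ~ log(ep$baseline_mm[ok])))[2])
}

# Smooth unit-variance 1D noise traces (participants x time).
smooth_traces <- function(n, T, kernel_sd = 3) {
  k <- dnorm(seq(-3 * kernel_sd, 3 * kernel_sd), sd = kernel_sd)
  k <- k / sqrt(sum(k^2))
  m <- matrix(rnorm(n * (T + length(k))), n)
  out <- t(apply(m, 1, function(x) convolve(x, k, type = "filter")))
  out[, seq_len(T), drop = FALSE]
}
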