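test_that("epoching produces 3500-sample baseline-corrected epochs", {
  s <- pupil_series(rep(4, 10000), 1000)
  ep <- epoch_tones(s, onsets_ms = c(1000, 4000))
  expect_equal(nrow(ep), 2)
  expect_true(all(vapply(ep$trace, length, integer(1)) == 3500))
  expect_true(all(abs(unlist(ep$trace)) < 1e-12))  # constant -> flat zero
  expect_equal(ep$baseline_mm, c(4, 4))

  # onset too close to the series start: incomplete baseline -> dropped
  expect_warning(ep2 <- epoch_tones(s, onsets_ms = c(200, 3000)), "dropped")
  expect_equal(nrow(ep2), 1)

  # epoching is translation invariant
  set.seed(2)
  v <- 4 + cumsum(rnorm(8000, 0, 0.01))
  a <- epoch_tones(pupil_series(v, 1000, t0_ms = 0), 2000)
  b <- epoch_tones(pupil_series(v, 1000, t0_ms = 700), 2700)
  expect_equal(a$trace[[1]], b$trace[[1]])
  expect_equal(a$peak_mm, b$peak_mm)
})

test_that("epoch peak is the maximal corrected dilation after onset", {
  n <- 8000
  t <- seq_len(n) - 1
  v <- rep(4, n)
  on <- 2000
  v <- v + 0.5 * exp(-((t - on - 1000) / 300)^2)  # bump peaking 1 s post-tone
  ep <- epoch_tones(pupil_series(v, 1000), on)
  expect_equal(ep$peak_mm, 0.5, tolerance = 1e-3)

  masked <- pupil_series(v, 1000, valid = c(rep(FALSE, 2500), rep(TRUE, n - 2500)))
  epf <- epoch_tones(masked, on)
  expect_true(epf$flagged)
})

test_that("log-log regression recovers the baseline exponent exactly", {
  set.seed(10)
  ids <- rep(1:5, each = 40)
  x <- runif(200, 3, 6)

  ident <- baseline_bias_test(x, x, ids)
  expect_equal(unname(ident$beta_x), rep(1, 5), tolerance = 1e-10)
  expect_equal(ident$t_stat, 0)

  y <- 0.7 * x^0.8
  pow <- baseline_bias_test(x, y, ids)
  expect_equal(unname(pow$beta_x) - 1, rep(-0.2, 5), tolerance = 1e-10)

  # Eq-4 consistency: exp(intercept) * x^(beta-1) reproduces y/x exactly
  for (g in 1:5) {
    i <- ids == g
    pred <- exp(pow$intercepts[g]) * x[i]^(pow$beta_x[g] - 1)
    expect_equal(pred, y[i] / x[i], tolerance = 1e-10)
  }

  # scale-free: rescaling baselines changes intercepts, never beta
  scaled <- baseline_bias_test(3 * x, y, ids)
  expect_equal(scaled$beta_x, pow$beta_x, tolerance = 1e-9)

  single <- baseline_bias_test(x[1:40], y[1:40], rep(1, 40))
  expect_false(single$group_test_available)
  expect_equal(unname(single$beta_x), 0.8, tolerance = 1e-10)

  # non-positive observations are excluded and counted
  y2 <- y; y2[1] <- -0.1
  expect_equal(baseline_bias_test(x, y2, ids)$n_excluded, 1)
})

test_that("repeated-measures correlation finds the common within slope", {
  set.seed(4)
  ids <- rep(1:6, each = 20)
  x <- rnorm(120)
  offs <- rep(rnorm(6, sd = 5), each = 20)

  perfect <- suppressWarnings(rm_correlation(x, x + offs, ids))
  expect_equal(perfect$r_rm, 1, tolerance = 1e-8)
  expect_equal(perfect$df, 120 - 6 - 1)

  anti <- suppressWarnings(rm_correlation(x, -x + offs, ids))
  expect_equal(anti$r_rm, -1, tolerance = 1e-8)

  # independent x and y: near-zero coefficient, calibrated p
  set.seed(9)
  ids_n <- rep(1:20, each = 50)
  xn <- rnorm(1000); yn <- rnorm(1000) + rep(rnorm(20), each = 50)
  null <- rm_correlation(xn, yn, ids_n)
  expect_lt(abs(null$r_rm), 0.1)

  expect_error(rm_correlation(x[1:20], x[1:20], ids[1:20]), "2 participants")
  expect_error(rm_correlation(c(1, 1, 2, 3), c(1, 2, 3, 4), c(1, 1, 2, 2)),
               "variance")
})

test_that("time-on-task screening detrends only significant trends", {
  set.seed(5)
  ids <- rep(1:8, each = 30)
  trial <- rep(1:30, 8)

  # clear positive trend with noise: detrended residual slopes are ~0
  y <- 5 + 0.05 * trial + rep(rnorm(8), each = 30) + rnorm(240, 0, 0.05)
  res <- detrend_time_on_task(y, trial, ids)
  expect_true(res$applied)
  expect_equal(res$slope, 0.05, tolerance = 0.05)
  for (g in 1:8) {
    i <- ids == g
    expect_equal(unname(coef(lm(res$values[i] ~ trial[i]))[2]), 0,
                 tolerance = 1e-10)
  }

  # noise-free linear data: slope recovered exactly
  y2 <- 5 + 0.01 * trial
  res2 <- detrend_time_on_task(y2, trial, ids)
  expect_equal(res2$slope, 0.01, tolerance = 1e-10)

  # slope exactly 0: values returned unchanged
  y3 <- rep(rnorm(8), each = 30)
  res3 <- detrend_time_on_task(y3, trial, ids)
  expect_identical(res3$values, y3)
})

test_that("behavioural summary applies RT exclusion and the accuracy rule", {
  resp <- function(kind, responded, rt) {
    data.frame(kind = kind, responded = responded, rt_ms = rt)
  }
  # 95% hits, 1% false alarms -> accuracy 94%
  ev <- rbind(
    resp(rep("target", 100), c(rep(TRUE, 95), rep(FALSE, 5)),
         c(rep(400, 95), rep(NA, 5))),
    resp(rep("standard", 100), c(TRUE, rep(FALSE, 99)),
         c(350, rep(NA, 99)))
  )
  s <- behavioural_summary(ev)
  expect_equal(s$hit_pct, 95)
  expect_equal(s$false_alarm_pct, 1)
  expect_equal(s$accuracy_pct, 94)
  # false alarms never enter the RT statistics
  expect_equal(s$mean_rt_ms, 400)

  # RT outlier exclusion: with multiplier 2 nothing removed, with 1 one RT
  ev2 <- resp(rep("target", 4), rep(TRUE, 4), c(300, 310, 320, 900))
  s2 <- behavioural_summary(ev2)
  expect_equal(s2$n_rt_excluded, 0)
  expect_equal(s2$mean_rt_ms, mean(c(300, 310, 320, 900)))
  s2b <- behavioural_summary(ev2, rt_sd_multiplier = 1)
  expect_equal(s2b$n_rt_excluded, 1)
  expect_equal(s2b$mean_rt_ms, mean(c(300, 310, 320)))

  # no presses to standards -> zero false alarms; no targets -> flag
  s3 <- behavioural_summary(resp(rep("standard", 10), rep(FALSE, 10),
                                 rep(NA, 10)))
  expect_equal(s3$false_alarm_pct, 0)
  expect_false(s3$accuracy_defined)
})
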