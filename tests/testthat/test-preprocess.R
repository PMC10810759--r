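test_that("dilation-speed filter masks spikes and spares flat data", {
  flat <- pupil_series(rep(4, 50), 60)
  expect_identical(dilation_speed_filter(flat)$valid, flat$valid)

  spiky_v <- rep(4, 50); spiky_v[25] <- 5
  spiky <- pupil_series(spiky_v, 60)
  expect_false(dilation_speed_filter(spiky)$valid[25])

  two <- pupil_series(c(4, 8), 60)
  expect_identical(dilation_speed_filter(two)$valid, two$valid)

  # filters only mask, never alter values
  out <- dilation_speed_filter(spiky)
  expect_identical(out$values_mm, spiky$values_mm)
})

test_that("trend-line filter masks isolated outliers within four passes", {
  t <- (0:199) * 1000 / 60
  smooth <- 4 + 0.3 * sin(2 * pi * t / 5000)
  s0 <- pupil_series(smooth, 60)
  expect_identical(trendline_filter(s0)$valid, s0$valid)

  v <- smooth
  bad <- c(20, 60, 100, 140, 180)
  v[bad] <- v[bad] + c(0.8, -0.8, 0.8, -0.8, 0.8)
  s1 <- pupil_series(v, 60)
  out <- trendline_filter(s1)
  expect_true(all(!out$valid[bad]))

  expect_identical(trendline_filter(s1, passes = 0)$valid, s1$valid)
  w <- testthat::capture_warnings(
    trendline_filter(pupil_series(c(4, 4, 4), 60,
                                  valid = c(TRUE, TRUE, FALSE))))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 4)  # every pass reports the skip
})

test_that("island removal applies the width and gap rules at 1000 Hz", {
  mk <- function(pattern) pupil_series(rep(4, length(pattern)), 1000,
                                       valid = pattern)
  # 30 ms island between 60 ms gaps -> removed
  p1 <- c(rep(TRUE, 100), rep(FALSE, 60), rep(TRUE, 30), rep(FALSE, 60),
          rep(TRUE, 100))
  out1 <- remove_islands(mk(p1))
  expect_true(all(!out1$valid[161:190]))
  expect_true(all(out1$valid[1:100]))

  # 70 ms run exceeds the maximum island width -> kept
  p2 <- c(rep(TRUE, 100), rep(FALSE, 60), rep(TRUE, 70), rep(FALSE, 60),
          rep(TRUE, 100))
  expect_true(all(remove_islands(mk(p2))$valid[161:230]))

  # 30 ms run between 30 ms gaps (not > 40 ms) -> kept
  p3 <- c(rep(TRUE, 100), rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 30),
          rep(TRUE, 100))
  expect_true(all(remove_islands(mk(p3))$valid[131:160]))

  # island at the series edge: edge counts as a gap
  p4 <- c(rep(TRUE, 30), rep(FALSE, 60), rep(TRUE, 100))
  expect_true(all(!remove_islands(mk(p4))$valid[1:30]))
})

test_that("binocular merge averages and offset-adjusts single-eye samples", {
  lv <- c(4.0, 4.0, NA, 4.0)
  rv <- c(4.4, NA, 4.4, 4.4)
  left <- pupil_series(lv, 60)
  right <- pupil_series(rv, 60)
  m <- merge_eyes(left, right)
  # both valid -> plain mean; offset (right - left) = +0.4 here
  expect_equal(m$values_mm[1], 4.2)
  expect_equal(m$values_mm[2], 4.2)  # left only: 4.0 + 0.4/2
  expect_equal(m$values_mm[3], 4.2)  # right only: 4.4 - 0.4/2
  expect_true(all(m$valid))

  both_na <- merge_eyes(pupil_series(c(4, NA), 60), pupil_series(c(4.2, NA), 60))
  expect_false(both_na$valid[2])

  expect_error(merge_eyes(left, pupil_series(rv, 120)), "time base")

  # spec worked example: left 4.0 valid, offset +0.2 -> 4.1
  l2 <- pupil_series(c(4.0, 4.0, 4.0), 60)
  r2 <- pupil_series(c(4.2, 4.2, NA), 60)
  expect_equal(merge_eyes(l2, r2)$values_mm[3], 4.1)
})

test_that("resampling yields the exact grid and the filter behaves", {
  # 15 s of 60 Hz -> 15,000 analysis samples
  s <- pupil_series(rep(4, 900), 60)
  out <- resample_smooth(s)
  expect_equal(length(out), 15000)
  expect_equal(out$fs_hz, 1000)
  expect_true(all(abs(out$values_mm - 4) < 1e-3))  # DC preserved

  # 10 Hz component attenuated below 5% (measured away from the edges)
  t <- (0:1799) * 1000 / 60
  s10 <- pupil_series(4 + sin(2 * pi * 10 * t / 1000), 60)
  o10 <- resample_smooth(s10)
  mid <- 10000:20000
  expect_lt(max(abs(o10$values_mm[mid] - 4)), 0.05)

  # missing spans stay flagged even though values are interpolated
  v <- rep(4, 300); ok <- rep(TRUE, 300); ok[100:140] <- FALSE
  sm <- resample_smooth(pupil_series(v, 60, valid = ok))
  expect_true(any(!sm$valid))
  expect_true(all(is.finite(sm$values_mm)))

  expect_error(resample_smooth(pupil_series(c(4, rep(NA, 10)), 60)), "valid")
})

test_that("trial and session rejection use strict thresholds", {
  n <- 2300  # one trial: baseline [0,1000), modulation [1000,2300) at 1000 Hz
  mk_trial <- function(frac_missing) {
    ok <- rep(TRUE, n)
    ok[seq_len(round(frac_missing * n))] <- FALSE
    pupil_series(rep(4, n), 1000, valid = sample(ok))
  }
  trials <- data.frame(trial = 1, baseline_start_ms = 0,
                       modulation_end_ms = 2300)
  set.seed(1)
  expect_true(reject_trials(mk_trial(0.31), trials)$excluded)
  expect_false(reject_trials(mk_trial(0.30), trials)$excluded)  # strict >

  # session flag: >50% of trials excluded
  ok <- rep(TRUE, 10000)
  ok[1:4000] <- FALSE  # trials 1-4 fully missing, 5-10 clean (1000 ms trials)
  s <- pupil_series(rep(4, 10000), 1000, valid = ok)
  tr10 <- data.frame(trial = 1:10, baseline_start_ms = (0:9) * 1000,
                     modulation_end_ms = (1:10) * 1000)
  r <- reject_trials(s, tr10)
  expect_equal(sum(r$excluded), 4)
  expect_false(attr(r, "session_excluded"))   # 40% not > 50%
  ok[1:6000] <- FALSE
  r2 <- reject_trials(pupil_series(rep(4, 10000), 1000, valid = ok), tr10)
  expect_true(attr(r2, "session_excluded"))   # 60% > 50%
})

test_that("baseline correction subtracts or divides the pre-phase mean", {
  v <- c(rep(4, 2000), rep(4.3, 1000))
  s <- pupil_series(v, 1000)
  bc <- baseline_correct(s, 2000, 3000)
  expect_equal(bc$baseline_mm, 4)
  expect_true(all(abs(bc$trace$values_mm - 0.3) < 1e-12))
  expect_false(bc$flagged)

  rel <- baseline_correct(pupil_series(c(rep(4, 2000), rep(4.5, 1000)), 1000),
                          2000, 3000, mode = "relative")
  expect_true(all(abs(rel$trace$values_mm - 0.125) < 1e-12))

  const <- baseline_correct(pupil_series(rep(4, 3000), 1000), 2000, 3000)
  expect_true(all(const$trace$values_mm == 0))

  gone <- pupil_series(v, 1000, valid = c(rep(FALSE, 2000), rep(TRUE, 1000)))
  expect_true(baseline_correct(gone, 2000, 3000)$flagged)
})

test_that("each filter's mask equals its brute-force oracle exactly", {
  for (seed in 1:12) {
    fx <- make_fixture(seed)
    expect_identical(dilation_speed_filter(fx$series)$valid,
                     oracle_speed_mask(fx$t, fx$v, fx$valid),
                     label = sprintf("speed mask, fixture %d", seed))
    expect_identical(trendline_filter(fx$series)$valid,
                     oracle_trend_mask(fx$t, fx$v, fx$valid, fx$fs),
                     label = sprintf("trend mask, fixture %d", seed))
    expect_identical(remove_islands(fx$series)$valid,
                     oracle_island_mask(fx$valid, fx$fs),
                     label = sprintf("island mask, fixture %d", seed))
    fx2 <- make_fixture(seed + 100)
    m <- merge_eyes(fx$series, fx2$series)
    expect_equal(m$values_mm,
                 oracle_merge_values(fx$v, fx$valid, fx2$v, fx2$valid),
                 label = sprintf("merge values, fixture %d", seed))
  }
})

test_that("the mask cascade is idempotent on clean data", {
  t <- (0:299) * 1000 / 60
  clean <- pupil_series(4 + 0.2 * sin(2 * pi * t / 8000), 60)
  once <- remove_islands(trendline_filter(dilation_speed_filter(clean)))
  twice <- remove_islands(trendline_filter(dilation_speed_filter(once)))
  expect_identical(once$valid, twice$valid)
  expect_identical(once$values_mm, clean$values_mm)
})
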