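test_that("training days produce the printed trial counts and phase timing", {
  d1 <- build_training_schedule(1, rng_seed = 3)
  expect_equal(unname(table(d1$condition)["up"]), 30, ignore_attr = TRUE)
  expect_equal(unname(table(d1$condition)["down"]), 30, ignore_attr = TRUE)
  expect_equal(length(unique(d1$block)), 6)
  expect_true(all(table(d1$block) == 10))
  # phase durations: instruction 2 s, baseline 7 s, modulation 15 s
  expect_true(all(d1$baseline_start_ms - d1$trial_start_ms == 2000))
  expect_true(all(d1$modulation_start_ms - d1$baseline_start_ms == 7000))
  expect_true(all(d1$modulation_end_ms - d1$modulation_start_ms == 15000))
  expect_true(all(d1$trial_end_ms - d1$modulation_end_ms == 7000))  # fb + break
  expect_true(all(d1$feedback_mode == "online"))

  nf <- build_training_schedule("no_feedback_post", rng_seed = 3)
  expect_equal(sum(nf$condition == "up"), 20)
  expect_equal(sum(nf$condition == "down"), 20)
  expect_true(all(nf$feedback_mode == "none"))

  yk <- build_training_schedule(2, group = "yoked", rng_seed = 3)
  expect_true(all(yk$feedback_mode == "yoked"))

  empty <- build_training_schedule(1, rng_seed = 3, blocks_per_condition = 0)
  expect_equal(nrow(empty), 0)

  expect_error(build_training_schedule("day 9", rng_seed = 1), "unknown")
})

test_that("scanner schedule counterbalances 32 trials per condition", {
  s <- build_fmri_schedule("brainstem", rng_seed = 9)
  expect_equal(sum(s$condition == "up"), 32)
  expect_equal(sum(s$condition == "down"), 32)
  expect_equal(length(unique(s$run)), 4)
  expect_true(all(s$modulation_start_ms - s$baseline_start_ms == 7500))
  expect_true(all(s$modulation_end_ms - s$modulation_start_ms == 15000))
  expect_true(all(s$feedback_dur_ms == 2500))
  brk <- s$trial_end_ms - s$modulation_end_ms - s$feedback_dur_ms
  expect_true(all(brk >= 6000 & brk <= 9000))

  one <- build_fmri_schedule("wholebrain", rng_seed = 9, n_runs = 1)
  expect_equal(sum(one$condition == "up"), 8)
  expect_equal(sum(one$condition == "down"), 8)

  # identical jitter sequence on repeated call with the same seed
  expect_identical(build_fmri_schedule("brainstem", rng_seed = 4),
                   build_fmri_schedule("brainstem", rng_seed = 4))
})

test_that("oddball schedule reproduces session totals and tone constraints", {
  s <- build_oddball_schedule(rng_seed = 21)
  tones <- schedule_tones(s)
  expect_equal(nrow(s), 117)
  expect_equal(sum(tones$kind == "target"), 186)
  expect_equal(sum(tones$kind == "standard"), 750)
  expect_equal(nrow(tones), 8 * nrow(s))  # tone totals conserve
  expect_true(all(table(s$condition) == 39))

  # per-trial structure, verified exhaustively
  for (tr in split(tones, tones$trial)) {
    expect_identical(tr$kind[1], "standard")
    n_tg <- sum(tr$kind == "target")
    expect_true(n_tg >= 1 && n_tg <= 2)
    tg_pos <- which(tr$kind == "target")
    if (n_tg == 2) expect_true(diff(tg_pos) > 2)
    m0 <- s$modulation_start_ms[s$trial == tr$trial[1]]
    isis <- diff(c(m0, tr$onset_ms))
    expect_true(all(isis >= 1800 & isis <= 2200))
  }

  # minimum onset gap between any two targets across the whole session
  tg <- sort(tones$onset_ms[tones$kind == "target"])
  expect_true(min(diff(tg)) >= 5400)

  # identical tone patterns across the three conditions
  pat <- function(cond) {
    tr <- s$trial[s$condition == cond]
    unlist(lapply(tr, function(x) tones$kind[tones$trial == x]))
  }
  expect_identical(pat("up"), pat("down"))
  expect_identical(pat("up"), pat("control"))

  # control trials carry no feedback phase
  expect_true(all(s$feedback_dur_ms[s$condition == "control"] == 0))
  expect_true(all(s$feedback_dur_ms[s$condition != "control"] == 2000))

  expect_identical(build_oddball_schedule(rng_seed = 2),
                   build_oddball_schedule(rng_seed = 2))
})

test_that("block order is pseudorandomized in condition triplets", {
  for (seed in 1:5) {
    s <- build_oddball_schedule(rng_seed = seed)
    blocks <- unique(s[, c("block", "condition")])
    blocks <- blocks[order(blocks$block), ]
    for (g in 1:3) {
      trip <- blocks$condition[(3 * g - 2):(3 * g)]
      expect_setequal(trip, c("up", "down", "control"))
    }
  }
})

test_that("infeasible oddball configurations are rejected", {
  expect_error(build_oddball_schedule(rng_seed = 1, target_total = 936),
               "infeasible")
  expect_error(build_oddball_schedule(rng_seed = 1, target_total = 100),
               "divide")
  expect_error(build_oddball_schedule(rng_seed = 1, n_blocks = 8),
               "multiple of 3")
})

test_that("events serialization is complete and ordered", {
  s <- build_oddball_schedule(rng_seed = 3, n_blocks = 3, trials_per_block = 2,
                              target_total = 9)
  ev <- schedule_events(s)
  expect_true(all(c("onset_ms", "duration_ms", "trial", "condition",
                    "event_type") %in% names(ev)))
  expect_equal(sum(grepl("^tone_", ev$event_type)), 8 * nrow(s))
  expect_true(all(ev$duration_ms > 0))
  # phases tile each trial without overlap
  one <- ev[ev$trial == 1 & !grepl("^tone_", ev$event_type), ]
  expect_equal(sum(one$duration_ms),
               s$trial_end_ms[1] - s$trial_start_ms[1])
})
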