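#' @name paradigm
#' @title Experiment schedules for pupil self-regulation paradigms
#'
#' @description
#' Generators for the three paradigms: multi-day biofeedback training,
#' scanner sessions, and the combined self-regulation + auditory oddball
#' task. All phase boundaries are integer milliseconds and intervals are
#' half-open `[start, end)`. Schedules are pure functions of their
#' configuration and `rng_seed`.
NULL

# Phase duration templates (ms)
.training_phases <- c(instruction = 2000, baseline = 7000, modulation = 15000,
                      feedback = 2000, brk = 5000)
.fmri_phases <- c(baseline = 7500, modulation = 15000, feedback = 2500)
.oddball_phases <- c(instruction = 2000, baseline = 4000, modulation = 18000,
                     feedback = 2000, brk = 2000)

new_schedule <- function(trials, experiment, seed, tones = NULL) {
  trials <- tibble::as_tibble(trials)
  structure(trials, class = c("bf_schedule", class(trials)),
            experiment = experiment, seed = seed, tones = tones)
}

#' @export
#' @method print bf_schedule
print.bf_schedule <- function(x, ...) {
  cat(sprintf("<bf_schedule: %s> %d trials (seed %s)\n",
              attr(x, "experiment"), nrow(x), format(attr(x, "seed"))))
  NextMethod()
}

#' Tone events of an oddball schedule
#'
#' @param schedule a schedule built by [build_oddball_schedule()].
#' @return tibble with one row per tone: trial, tone index, kind
#'   (`standard`/`target`) and absolute onset in ms.
#' @export
schedule_tones <- function(schedule) {
  tones <- attr(schedule, "tones")
  if (is.null(tones)) stop("schedule carries no tone events", call. = FALSE)
  tones
}

trial_rows <- function(start_ms, durs, trial, block, condition, feedback_mode,
                       run = NA_integer_) {
  has_fb <- durs[["feedback"]] > 0
  tibble::tibble(
    trial = trial, run = run, block = block, condition = condition,
    feedback_mode = feedback_mode,
    trial_start_ms = start_ms,
    baseline_start_ms = start_ms + durs[["instruction"]],
    modulation_start_ms = start_ms + durs[["instruction"]] + durs[["baseline"]],
    modulation_end_ms = start_ms + durs[["instruction"]] + durs[["baseline"]] +
      durs[["modulation"]],
    feedback_dur_ms = if (has_fb) durs[["feedback"]] else 0,
    trial_end_ms = start_ms + sum(durs)
  )
}

#' Build a biofeedback training-day schedule
#'
#' Training days hold blocks of 10 trials per condition (3 up- and 3
#' downregulation blocks on days 1–3, i.e. 30 Up and 30 Down trials per day);
#' the no-feedback sessions hold 20 Up and 20 Down trials with all feedback
#' disabled. Trial phases: instruction 2 s, baseline 7 s, modulation 15 s,
#' post-trial feedback 2 s, break 5 s.
#'
#' @param day one of `1`, `2`, `3`, `"no_feedback_pre"`, `"no_feedback_post"`.
#' @param group `"veridical"` (trials carry online feedback) or `"yoked"`
#'   (replayed feedback from a matched participant).
#' @param rng_seed integer seed; block order is a seeded permutation.
#' @param blocks_per_condition number of blocks per condition (default 3;
#'   0 yields an empty schedule).
#' @param trials_per_block trials per block (default 10).
#' @return a `bf_schedule` tibble, one row per trial.
#' @export
build_training_schedule <- function(day, group = c("veridical", "yoked"),
                                    rng_seed = 1L,
                                    blocks_per_condition = 3,
                                    trials_per_block = 10) {
  group <- match.arg(group)
  day <- as.character(day)
  known <- c("1", "2", "3", "no_feedback_pre", "no_feedback_post")
  if (length(day) != 1L || !day %in% known) {
    stop(sprintf("unknown training day '%s'; expected one of %s",
                 day, paste(known, collapse = ", ")), call. = FALSE)
  }
  no_fb <- startsWith(day, "no_feedback")
  if (no_fb) {
    blocks_per_condition <- 2   # 20 Up + 20 Down
    fb_mode <- "none"
  } else {
    fb_mode <- if (group == "veridical") "online" else "yoked"
  }
  n_blocks <- 2L * blocks_per_condition
  if (n_blocks == 0L) {
    return(new_schedule(trial_rows(0, .training_phases, 1, 1, "up", fb_mode)[0, ],
                        "training", rng_seed))
  }
  block_cond <- with_seed(rng_seed, {
    sample(rep(c("up", "down"), each = blocks_per_condition))
  })
  rows <- vector("list", n_blocks)
  t <- 0
  trial <- 0L
  for (b in seq_len(n_blocks)) {
    for (k in seq_len(trials_per_block)) {
      trial <- trial + 1L
      rows[[trial]] <- trial_rows(t, .training_phases, trial, b, block_cond[b],
                                  fb_mode)
      t <- t + sum(.training_phases)
    }
  }
  new_schedule(do.call(rbind, rows), "training", rng_seed)
}

#' Build a scanner-session schedule
#'
#' Four runs, each with two blocks per condition of four trials, giving 32
#' trials per condition. Phases: baseline 7.5 s, modulation 15 s, post-trial
#' feedback 2.5 s, break uniformly jittered in 6–9 s. A 2 s condition cue
#' opens each block and a 10 s rest follows it; block order alternates
#' between runs so conditions are counterbalanced.
#'
#' @param session `"brainstem"` or `"wholebrain"` (timing is identical; the
#'   label is recorded for provenance).
#' @param rng_seed integer seed controlling the break jitter.
#' @param n_runs number of runs (default 4).
#' @param blocks_per_condition_per_run default 2.
#' @param trials_per_block default 4.
#' @param start_condition condition of the first block of run 1.
#' @return a `bf_schedule` tibble, one row per trial.
#' @export
build_fmri_schedule <- function(session = c("brainstem", "wholebrain"),
                                rng_seed = 1L, n_runs = 4,
                                blocks_per_condition_per_run = 2,
                                trials_per_block = 4,
                                start_condition = c("up", "down")) {
  session <- match.arg(session)
  start_condition <- match.arg(start_condition)
  stopifnot(n_runs >= 1, blocks_per_condition_per_run >= 1, trials_per_block >= 1)
  other <- setdiff(c("up", "down"), start_condition)
  n_blocks_run <- 2L * blocks_per_condition_per_run
  rows <- list()
  with_seed(rng_seed, {
    t <- 0
    trial <- 0L
    block_id <- 0L
    for (r in seq_len(n_runs)) {
      first <- if (r %% 2 == 1) start_condition else other
      order_run <- rep(c(first, setdiff(c("up", "down"), first)),
                       blocks_per_condition_per_run)
      for (b in seq_len(n_blocks_run)) {
        block_id <- block_id + 1L
        t <- t + 2000  # block condition cue
        for (k in seq_len(trials_per_block)) {
          trial <- trial + 1L
          brk <- round(runif(1, 6000, 9000))
          durs <- c(instruction = 0, .fmri_phases, brk = brk)
          rows[[trial]] <- trial_rows(t, durs, trial, block_id, order_run[b],
                                      "post_only", run = r)
          t <- t + sum(durs)
        }
        t <- t + 10000  # inter-block rest
      }
    }
  })
  new_schedule(do.call(rbind, rows), paste0("fmri_", session), rng_seed)
}

# Feasible target positions within a trial: first tone is a standard, and
# two targets must be separated by >= `min_sb` standards.
sample_target_positions <- function(n_targets, tones_per_trial, min_sb) {
  slots <- 2:tones_per_trial
  if (n_targets == 1) return(sample(slots, 1))
  pairs <- expand.grid(i = slots, j = slots)
  pairs <- pairs[pairs$j - pairs$i > min_sb, , drop = FALSE]
  if (nrow(pairs) == 0) {
    stop("infeasible tone constraints: no target placement satisfies the ",
         "minimum-standards rule", call. = FALSE)
  }
  p <- pairs[sample(nrow(pairs), 1), ]
  c(p$i, p$j)
}

#' Build the self-regulation + auditory oddball schedule
#'
#' Nine blocks of 13 trials, one condition (`up`, `down`, `control`) per
#' block and three blocks per condition, giving 117 trials. Each trial's
#' modulation phase carries 8 tones (one or two targets, the rest standards);
#' the first tone is always a standard, two targets are separated by at least
#' two standards (minimum target-to-target interval 5.4 s), and inter-tone
#' intervals are uniformly jittered in 1.8–2.2 s. The tone patterns (kinds
#' and jitters) are identical across the three conditions, so session totals
#' are exact: with the defaults, 186 targets and 750 standards. Block order
#' is pseudorandomized so that each condition appears once in every
#' consecutive triplet of blocks. Trial phases: instruction 2 s, baseline
#' 4 s, modulation 18 s, then feedback 2 s + break 2 s (self-regulation) or a
#' 4 s break (control, which carries no feedback phase).
#'
#' @param rng_seed integer seed.
#' @param n_blocks total number of blocks; must be a multiple of 3.
#' @param trials_per_block default 13.
#' @param tones_per_trial default 8.
#' @param target_total total number of target tones across the session; must
#'   be divisible by 3 and feasible under the 1-or-2-targets-per-trial rule.
#' @param isi_range_ms inter-tone jitter range, default `c(1800, 2200)`.
#' @param min_standards_between_targets default 2.
#' @param block_gap_ms rest inserted between blocks (self-paced in practice),
#'   default 10000.
#' @return a `bf_schedule` tibble with a `tones` attribute
#'   (see [schedule_tones()]).
#' @export
build_oddball_schedule <- function(rng_seed = 1L, n_blocks = 9,
                                   trials_per_block = 13,
                                   tones_per_trial = 8,
                                   target_total = 186,
                                   isi_range_ms = c(1800, 2200),
                                   min_standards_between_targets = 2,
                                   block_gap_ms = 10000) {
  if (n_blocks %% 3 != 0) stop("`n_blocks` must be a multiple of 3", call. = FALSE)
  if (target_total %% 3 != 0) {
    stop("infeasible: `target_total` must divide evenly over the 3 conditions",
         call. = FALSE)
  }
  n_cond_blocks <- n_blocks %/% 3L
  trials_per_cond <- n_cond_blocks * trials_per_block
  targets_per_cond <- target_total %/% 3L
  n_two <- targets_per_cond - trials_per_cond
  if (n_two < 0 || n_two > trials_per_cond) {
    stop(sprintf(paste0(
      "infeasible: %d targets per condition cannot be placed in %d trials ",
      "with one or two targets per trial"), targets_per_cond, trials_per_cond),
      call. = FALSE)
  }
  min_sb <- min_standards_between_targets
  conds <- c("up", "down", "control")

  with_seed(rng_seed, {
    # Shared per-condition tone patterns: kinds + jitters.
    two_target <- rep(FALSE, trials_per_cond)
    two_target[sample(trials_per_cond, n_two)] <- TRUE
    patterns <- lapply(seq_len(trials_per_cond), function(k) {
      kinds <- rep("standard", tones_per_trial)
      pos <- sample_target_positions(if (two_target[k]) 2 else 1,
                                     tones_per_trial, min_sb)
      kinds[pos] <- "target"
      isis <- round(runif(tones_per_trial, isi_range_ms[1], isi_range_ms[2]))
      list(kinds = kinds, rel_onsets = cumsum(isis))
    })
    # Pseudorandom block order: all three conditions in every triplet.
    repeat {
      block_cond <- sample(rep(conds, n_cond_blocks))
      ok <- all(vapply(seq_len(n_cond_blocks), function(g) {
        length(unique(block_cond[(3 * g - 2):(3 * g)])) == 3
      }, logical(1)))
      if (ok) break
    }

    rows <- list()
    tone_rows <- list()
    t <- 0
    trial <- 0L
    seen <- stats::setNames(rep(0L, 3), conds)
    for (b in seq_len(n_blocks)) {
      cond <- block_cond[b]
      for (k in seq_len(trials_per_block)) {
        trial <- trial + 1L
        seen[cond] <- seen[cond] + 1L
        pat <- patterns[[seen[cond]]]
        is_ctrl <- cond == "control"
        durs <- .oddball_phases
        if (is_ctrl) {
          durs[["feedback"]] <- 0
          durs[["brk"]] <- 4000
        }
        row <- trial_rows(t, durs, trial, b, cond,
                          if (is_ctrl) "none" else "post_only")
        rows[[trial]] <- row
        tone_rows[[trial]] <- tibble::tibble(
          trial = trial, tone = seq_len(tones_per_trial),
          kind = pat$kinds,
          onset_ms = row$modulation_start_ms + pat$rel_onsets
        )
        t <- t + sum(durs)
      }
      t <- t + block_gap_ms
    }
    sched <- new_schedule(do.call(rbind, rows), "oddball", rng_seed,
                          tones = do.call(rbind, tone_rows))
    check_oddball_schedule(sched, isi_range_ms, min_sb, tones_per_trial)
    sched
  })
}

# Invariant checks run on every generated oddball schedule.
check_oddball_schedule <- function(sched, isi_range_ms, min_sb, tones_per_trial) {
  tones <- attr(sched, "tones")
  stopifnot(nrow(tones) == tones_per_trial * nrow(sched))
  for (tr in split(tones, tones$trial)) {
    stopifnot(tr$kind[1] == "standard")
    isis <- diff(c(sched$modulation_start_ms[sched$trial == tr$trial[1]],
                   tr$onset_ms))
    stopifnot(all(isis >= isi_range_ms[1]), all(isis <= isi_range_ms[2]))
    tg <- which(tr$kind == "target")
    if (length(tg) > 1) stopifnot(all(diff(tg) > min_sb))
  }
  invisible(sched)
}

#' Serialize a schedule as a long events table
#'
#' Produces the events dialect shared by the readers/writers: one row per
#' phase (and tone, for oddball schedules) with absolute onset and duration.
#'
#' @param schedule a `bf_schedule`.
#' @return tibble with columns `onset_ms`, `duration_ms`, `trial`,
#'   `condition`, `event_type`.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "bf_schedule"))
  ev <- lapply(seq_len(nrow(schedule)), function(i) {
    r <- schedule[i, ]
    ph <- tibble::tibble(
      onset_ms = c(r$trial_start_ms, r$baseline_start_ms, r$modulation_start_ms,
                   r$modulation_end_ms,
                   r$modulation_end_ms + r$feedback_dur_ms),
      duration_ms = c(r$baseline_start_ms - r$trial_start_ms,
                      r$modulation_start_ms - r$baseline_start_ms,
                      r$modulation_end_ms - r$modulation_start_ms,
                      r$feedback_dur_ms,
                      r$trial_end_ms - r$modulation_end_ms - r$feedback_dur_ms),
      trial = r$trial, condition = r$condition,
      event_type = c("instruction", "baseline", "modulation", "feedback", "break")
    )
    ph[ph$duration_ms > 0, ]
  })
  ev <- do.call(rbind, ev)
  tones <- attr(schedule, "tones")
  if (!is.null(tones)) {
    cond <- schedule$condition[match(tones$trial, schedule$trial)]
    ev <- rbind(ev, tibble::tibble(
      onset_ms = tones$onset_ms, duration_ms = 100, trial = tones$trial,
      condition = cond, event_type = paste0("tone_", tones$kind)
    ))
    ev <- ev[order(ev$onset_ms, ev$trial), ]
  }
  tibble::as_tibble(ev)
}
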