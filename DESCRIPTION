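Package: pupilbf
Title: Pupil-Based Biofeedback: Feedback Engine, Pupillometry Preprocessing
    and Arousal Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for pupil-based biofeedback experiments in which
    participants learn to volitionally up- and downregulate their own pupil
    diameter. Provides generators and validators for the training, scanner
    and auditory-oddball trial schedules; a streaming quasi-real-time
    feedback engine with per-sample validation, dilation-speed gating and
    isoluminant constant-area ring geometry; the offline pupillometry
    cleaning cascade (dilation-speed and trend-line outlier rejection by
    median absolute deviation, island removal, binocular merging, zero-phase
    resampling and smoothing, trial rejection, baseline correction);
    condition-level arousal metrics (pupil modulation index, per-volume
    downsampling); heart-rate and heart-rate-variability metrics with a
    RETROICOR-style physiological-noise design-matrix builder; tone-locked
    evoked-response analysis with a log-log baseline-bias test,
    repeated-measures correlation and time-on-task detrending; sign-flip
    cluster permutation inference for one-dimensional time series with
    robust trimmed-mean comparisons; and a seeded closed-loop synthetic-data
    generator that gives every pipeline stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
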