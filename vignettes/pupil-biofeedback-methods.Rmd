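---
title: "Methods: pupil self-regulation, feedback display and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil self-regulation, feedback display and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilbf)
```

# The paradigm and its signal model

Under constant luminance, pupil diameter tracks the brain's arousal state:
slow ("tonic") baseline diameter and fast stimulus-evoked ("phasic")
dilations are widely used as non-invasive proxies of neuromodulatory
activity, most prominently of the noradrenergic locus coeruleus. Pupil-based
biofeedback turns this readout into a training signal: the participant sees
an isoluminant ring whose radius follows their own pupil in quasi real-time
and applies arousing or relaxing mental strategies to push it up or down.

`pupilbf` implements the full tool chain around this idea: the trial
schedules, the streaming display engine, the offline cleaning cascade, the
derived arousal/cardiac/oddball statistics, continuum-level inference for
pupil time-series, and a seeded synthetic generator that provides ground
truth for all of it. This vignette records the models and every place where
a genuine design decision had to be made.

# The streaming feedback engine

Each raw sample is validated (diameter inside 1.5–9 mm; the blink sentinel
−1 is always invalid) and then speed-gated against the last accepted sample.

**Velocity-threshold units.** The dilation-speed plausibility bound is
stored as 0.0027 mm/ms (= 2.7 mm/s). A bound of 0.0027 mm/s would reject
essentially every real sample pair — peak pupillary light-reflex
constriction velocities are of the order of millimetres per second — so the
per-millisecond reading is the physiologically coherent one. The value is a
configuration field (`engine_config(velocity_threshold = )`), not a
constant.

**Display smoothing.** The displayed value is the mean of the last two
accepted samples; with a single accepted sample that sample is shown, and
with none the previous frame is held. The single-sample rule is a choice:
averaging needs two points, and holding a blank display at trial start
would be indistinguishable from a dropout.

**Ring geometry.** The ring only moves in the trial's required direction;
wrong-direction changes clamp it to the baseline radius (`gated = TRUE`).
Thickness is set to `area / (2 * pi * radius)`, which conserves the annulus
pixel area exactly — the isoluminance requirement fixes the goal (constant
number of coloured pixels) but not the formula, and exact conservation is
the simplest rule that satisfies it. The mm→px display gain is nowhere
specified by the paradigm itself; the default maps ±1 mm to ±50 % of the
baseline radius and is configurable. Isoluminance is checked with
`Y = 0.2126 R + 0.7152 G + 0.0722 B` against the grey (150, 150, 150)
background with a default tolerance of 0.5 luminance units.

**Purity.** The engine is a pure fold over the sample stream: replaying a
stream reproduces the frame log bit-identically, which is what makes yoked
("replay") feedback and offline reconstruction possible.

# The offline cleaning cascade

The pipeline order is fixed: range/blink validation → dilation-speed filter
→ trend-line filter (4 passes) → island removal → binocular merge →
resampling/smoothing → trial rejection → baseline correction. Every filter
only ever masks samples; values are untouched until resampling.

* **Dilation speed.** Per valid sample, speed is the larger normalized
  absolute change toward its two valid neighbours, using actual inter-sample
  gaps (robust to timestamp jitter at 60 Hz). Samples with
  `speed > median + 12 * MAD` are masked. The MAD is the raw
  median-absolute-deviation without the 1.4826 Gaussian consistency
  constant; the multiplier 12 is calibrated against that raw form.
* **Trend line.** The trend is defined as the 4 Hz zero-phase low-pass of
  the linear interpolation through currently valid samples — the paradigm
  names a "trend line" without defining one, and this choice reuses the
  smoothing filter already in the pipeline. Deviations are thresholded with
  the same `median + 12 * MAD` rule, repeated in exactly four passes; the
  multiplier for this stage is its own argument since the shared value is
  an interpretation.
* **Numerical floors.** Both MAD filters degenerate when the dispersion
  estimate collapses to ~0 (noise-free or near-constant data): the
  threshold then masks pure floating-point noise, including every genuine
  slow change. Two floors make the rules total: speeds below 0.001 mm/ms
  (1 mm/s, well under plausible artifact velocities) and trend deviations
  below 0.01 mm (under eye-tracker quantization) are never masked. On any
  realistically noisy recording the adaptive threshold is far above both
  floors and they are inert.
* **Islands.** Valid runs no wider than 50 ms bordered on both sides by
  gaps wider than 40 ms are removed; series edges count as gaps. Widths are
  sample counts × the sampling interval; all comparisons are strict
  (`> 40 ms`), as are the rejection thresholds below.
* **Binocular merge.** Where both eyes are valid the sample-wise mean is
  taken. Where one eye is missing, that eye's value is shifted by half the
  session-mean inter-eye offset so single-eye stretches stay on the
  binocular-mean scale instead of jumping by the anatomical left/right
  asymmetry.
* **Resampling and smoothing.** Valid samples are linearly interpolated
  onto the 1000 Hz grid (a 15 s modulation phase yields exactly 15,000
  samples) and smoothed with a 3rd-order Butterworth at 4 Hz applied
  forward–backward (zero phase; effective 6th-order magnitude). The filter
  runs on an odd-reflection padded copy because un-padded forward–backward
  filtering distorts the edges badly. Spans that were missing before
  interpolation stay flagged in the mask, so downstream rejection uses
  observed data only.
* **Rejection and baseline.** Trials with more than 30 % missing samples
  across baseline + modulation are excluded; a session with more than 50 %
  excluded trials is flagged. Baseline correction subtracts the mean of the
  last 1000 ms before modulation onset; relative mode divides the
  subtractive change by the baseline and is used for evoked-peak analyses.

All phase boundaries are integer milliseconds and all windows are half-open
`[start, end)`, so adjacent phases tile a trial without overlap.

# Arousal, cardiac and oddball statistics

The **pupil modulation index** is the mean over the modulation window of
the difference between baseline-corrected Up and Down traces (n = 15,000
points for full 15 s trials at 1000 Hz); it is linear and antisymmetric in
its arguments. For scanner analyses the absolute pupil trace is averaged in
half-open TR bins after shifting the pupil timestamps back by 1 s — the
pupil leads the haemodynamic response, so the shift aligns the pupil signal
with the BOLD it predicts; empty bins are linearly interpolated.

Cardiac metrics operate on R-R intervals whose **both** defining peaks fall
inside the analysis window: heart rate is the mean of 60/interval, RMSSD
the root mean square of successive interval differences, and pNN35 the
percentage of successive differences strictly greater than 35 ms. The
physiological-noise design matrix holds sine/cosine pairs for 4 cardiac and
4 respiratory harmonics plus, per interaction order k, pairs for both the
sum and difference combinations (`k*cardiac ± resp` and `k*resp ±
cardiac`) — 4 columns per interaction order — plus one heart-rate and one
respiration-volume column: 34 columns at orders (4, 4, 2, 2). The
interaction formula is a reconstruction: the named sets and the printed
total fix the column count, and sum/difference phase pairs are the standard
Fourier expansion of a product of cosines. Nuisance traces are per-volume.

**Epoching.** Tone-locked epochs run from −0.5 to +3 s (half-open: 3500
samples at 1000 Hz), are normalized to the mean of the 500 ms before onset,
and record the maximal corrected dilation in the open interval (0, 3000) ms
as the peak — the peak definition needs a search window and the full
post-onset epoch is the least committal choice.

**Baseline-bias test.** Correlating a relative change `y/x` with `x` is
biased by regression to the mean, but the exponent of
`y = exp(c) * x^beta` is estimated without bias by the per-participant
regression `lm(log(y) ~ log(x))`; `beta - 1 = 0` means the baseline has no
influence on the *relative* peak. The group test is a one-sample t-test of
per-participant slopes against 1. Non-positive values cannot enter the log
domain and are excluded with a reported count.

**Repeated-measures correlation** uses the shared-slope
analysis-of-covariance formulation (participant dummies + one common
slope); `r` takes the slope's sign and `df = N - k - 1`.

**Time-on-task.** A mixed model (fixed trial-index slope, random
per-participant intercept, REML via lmerTest) screens for a linear trend;
when the slope is significant at two-tailed 0.05 the values are detrended
per participant by least squares, keeping the participant mean so the
values stay in interpretable units (removing the mean as well would change
nothing downstream — correlations are location-invariant). Degenerate
noise-free inputs break the mixed fit, so a fixed-effects fit with
participant dummies is the documented fallback. Reaction-time outliers are
excluded at participant mean ± 2 SD computed across all conditions (the
per-condition alternative is one argument away); accuracy is
%hits − %false alarms.

# Continuum-level inference

Random-field inference for 1D pupil trajectories is replaced by a
**sign-flip cluster-mass permutation test**: pointwise paired t statistics;
cluster-forming threshold = the (1 − α) quantile of the permutation
distribution of the maximum |t| (the analogue of a random-field critical
value); cluster mass = the sum of suprathreshold |t|; cluster p = the
proportion of permutations (plus one) whose maximum cluster mass reaches
the observed mass, ties counted with ≥. The permutation route was chosen
deliberately: it is exact for small samples, needs no smoothness
estimation, and its α calibration is itself a test in the suite (500 null
simulations). It is *not* numerically identical to random-field thresholds;
results carry their seed and permutation count for reproducibility.
Zero-variance time points (identical traces) are assigned t = 0 rather than
0/0. Robust comparisons use 20 % trimmed means (`floor(0.2 n)` trimmed per
tail) and Yuen's paired statistic on winsorized variances; the full robust
factorial ANOVA machinery is out of scope — contrasts are pairwise.

# The synthetic test-bed

`simulate_session()` generates, per participant: a baseline diameter drawn
between participants (4.5 ± 0.5 mm); a condition effect (±0.4 mm at
asymptote) entering through a logistic onset ramp (midpoint 1 s, time
constant 0.3 s) and leaving through a 1 s exponential decay; band-limited
1/f arousal noise (0.002–0.05 Hz, sd 0.04 mm) common to both eyes; white
per-eye sensor noise (0.008 mm); a linear time-on-task drift; evoked
dilations at tone onsets with a gamma kernel (shape 8, mode 0.8 s — the
response has essentially returned to baseline by 2 s, so 2 s inter-tone
intervals barely overlap) and amplitude proportional to the momentary
baseline raised to the configured exponent (0.8, i.e. β_x − 1 = −0.2);
blinks as −1 spans (15/min, 100–400 ms); R-R intervals Gaussian around
60000/HR with HR raised (lowered) by 2.5 bpm during Up (Down) modulation;
and reaction times increasing with pre-tone baseline and trial number.

**What the defaults are for.** The noise levels were fixed a priori from a
variance analysis of the recovery estimators, before any recovery test was
run. The binding constraint is the evoked-peak measurement: the peak is a
*maximum* over a 3 s window, and any within-epoch noise inflates it
additively, which biases the log-log slope. Keeping the slow-noise band
below 0.05 Hz (so it is nearly constant within a 3.5 s epoch and is removed
by the pre-tone baseline), the sensor noise at 0.008 mm (mostly removed by
the 4 Hz smoothing), and the evoked amplitude at 0.6 mm keeps that bias
small relative to the ±10 % recovery tolerance at the default cohort size
of 20. These levels are therefore *below* typical human recordings, and
deliberately so: the generator is a verification instrument, and a passing
recovery test establishes that the pipeline code is correct, not that the
method is robust to every feature of real data. Features the generator does
not emulate: gaze-dependent foreshortening of the pupil image, saccade- and
vergence-related artifacts, squinting, asymmetric or partial blinks,
non-stationary blink rates, drifting inter-eye offsets, and arrhythmic
cardiac events. Conclusions about those must come from real recordings.

All draws flow through the mandatory seed; identical configurations produce
byte-identical sessions, and the ground truth record returns every
generative quantity (including the ramp-integrated expected modulation
index) so recovery tests compare like with like.

# Problem sizes used by the test-suite

The suite verifies oracle equivalence on ≤ 200-sample fixtures
(loop-based reimplementations of every mask rule, exact equality), and runs
the stochastic recovery studies at the generator's default cohort size of
20 participants — full training sessions (60 trials) for the Up−Down and
heart-rate recoveries and full oddball sessions (117 trials, 936 tones) for
the β_x recovery — plus 500 null simulations (12 participants × 60 time
points, 200 sign-flip permutations each) for the cluster-test α
calibration. These sizes were chosen so the whole suite completes in a few
minutes while leaving the Monte-Carlo error well inside the stated
tolerances.

# Known limitations

* The feedback engine replays streams; it does not interface with
  eye-tracker hardware or guarantee 60 Hz wall-clock timing.
* R-peak detection is out of scope — peaks are an input (they come from
  dedicated ECG toolchains with manual correction in practice).
* The cluster permutation test covers paired (two-condition) contrasts;
  factorial repeated-measures designs on continua are not implemented.
* The baseline-bias estimator assumes strictly positive peaks; trials with
  non-positive evoked peaks (possible under heavy noise) are dropped, which
  can bias very noisy analyses — the count of exclusions is always
  reported.
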