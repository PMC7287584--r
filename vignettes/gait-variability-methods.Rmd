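---
title: "Measuring gait variability and complexity from force plates and wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait variability and complexity from force plates and wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gaitvar)
```

## The measurement problem

Stride-to-stride variation in gait timing is a clinically meaningful marker in
older adults: larger stride-duration variability predicts adverse health
outcomes in people who are apparently healthy when measured. The laboratory
reference for stride timing is a force plate, but wearable inertial
measurement units (IMUs) at the waist or ankle are what can realistically be
deployed outside the laboratory. `gaitvar` implements a complete measurement
chain for continuous (about 3-minute) walks recorded simultaneously on

* a summed force-plate array (3-D forces at 1000 Hz, both feet on the array),
* a waist-worn IMU (tri-axial accelerometer and gyroscope at 400 Hz), and
* an ankle-worn IMU (same specification, right shank),

plus the statistics used to judge test-retest reliability and
between-instrument agreement of the derived outcomes, and a synthetic signal
generator that provides ground-truth heel-strike and toe-off times for
validating every stage.

## Event detection

### Force plate

Because both feet load the same summed array, stance phases cannot be
segmented; heel-strikes are located instead:

1. All maximal runs of vertical force above 1.1 x body weight lasting at
   least 2.5 ms are found (`detect_force_peaks()`).
2. From each run's force maximum a 50 ms window extends backwards; the time
   of peak positive jerk (first time derivative of force, central
   difference) inside the window is a heel-strike candidate
   (`jerk_candidates()`). Windows reaching before the recording start are
   truncated. Candidates from the two force peaks of one stance are merged
   (within 250 ms, below any physiological step time, keeping the higher
   jerk).
3. Candidates whose jerk is below 0.3 x the mean of the 50 highest candidate
   jerks are discarded as false detections (`filter_false_candidates()`).
   The reference statistic for "the value of the 50 highest candidates" is
   the mean; a rank-based reading (the 50th-highest value itself) is
   available via `method = "rank"`.
4. Feet are assigned from the mediolateral force averaged over 150 ms after
   each candidate; by convention positive means right (`assign_foot()`,
   configurable via `right_sign`). Exact zeros tie-break to left and
   non-alternating label sequences raise a warning.

Consecutive right heel-strikes define right strides (`right_strides()`).

### Ankle IMU

The sagittal angular velocity of the shank shows a large positive mid-swing
peak flanked by negative troughs at toe-off (before) and heel-strike (after).
`detect_ankle_events()` finds swing peaks (default at least 100 deg/s,
separated by at least 0.5 s), takes the deepest local minimum within 0.4 s
after each peak as the heel-strike and the deepest within 0.4 s before it as
the toe-off, and refines each time with the vertex of a least-squares
parabola over 5 samples (the refinement is clamped to +/- 2 samples). The
window lengths, separation and swing threshold are this package's defaults,
validated against synthetic ground truth. `pair_ankle_events()` then removes
any heel-strike not followed by a toe-off and vice versa, keeping the
earliest event of each same-label run, so labels strictly alternate.

### Waist IMU

Orientation is estimated with the Madgwick gradient-descent filter
(`madgwick_orientation()`, IMU variant: gyroscope integration corrected by a
normalized gradient step of magnitude `beta` toward gravity alignment). The
filter gain is `beta = 0.1`, a standard choice for walking-speed movement.
Rather than starting at the identity quaternion and discarding a convergence
run-in, the filter is initialized from the gravity direction measured by the
first accelerometer samples (`init = "acc"`): this removes the start-up
transient entirely, which matters because a transient at the recording start
otherwise leaks through the matched filter and produces a spurious detection.
The magnetometer is ignored by default — extracting vertical acceleration
needs only the gravity direction, and heading is unobservable from gravity
alone but also irrelevant here.

Earth-frame vertical acceleration (`vertical_acceleration()`) is the rotated
accelerometer signal minus 1 g. Heel-strikes are detected by convolving it
with a 16 Hz Ricker (Mexican hat) wavelet — `ricker_kernel()` uses
`sigma = 1/(pi f sqrt(2))`, placing the kernel's spectral peak at the
requested frequency, sampled on +/- 4 sigma and de-meaned so the discrete
kernel is exactly admissible — then low-pass filtering with a zero-lag
4th-order 6 Hz Butterworth filter (a 2nd-order design run forward and
backward, the standard reading of "4th order zero-lag"), and keeping local
maxima whose topographic prominence exceeds 0.5 x the 80th percentile of all
local-maxima prominences. The percentile is taken over prominences (the
quantity the threshold multiplies); thresholding on peak heights instead is
available via `threshold_on = "height"`. Because the threshold is relative,
the detector is invariant to amplitude scaling. An 8 Hz wavelet
(`wavelet_hz = 8`) accommodates gait styles with softer impacts; it is a
plain configuration value, not an automatic fallback.

## Stride series and outcomes

`build_strides()` spans heel-strike `k` to `k + step`: `step = 1` for
single-foot series (force plate right foot, ankle), `step = 2` for the
waist's mixed-feet series. `median_ratio_filter()` keeps strides within
`median/1.25` to `median*1.25` of the median candidate duration; the median
is computed once and not re-estimated after filtering (the filter is
nevertheless idempotent on clean data). The band is two-sided — the
symmetric reading of "within a 1.25 ratio". Cross-instrument agreement uses
`match_events()` with a 0.2 s tolerance; matching is a sorted two-pointer
sweep, which is both greedy in time order and maximum-cardinality for
one-dimensional event times. `gait_outcomes()` reports the stride count,
mean, sample SD (n - 1 denominator, the usual choice in reliability work)
and CV% = SD/mean x 100.

## Multiscale entropy of the resultant acceleration

Complexity of the waist signal is computed from the resultant (vector-norm)
acceleration — gravity included, hence mounting-orientation invariant — in
non-overlapping 1-minute epochs, the remainder discarded
(`split_epochs()`).

Refined composite multiscale sample entropy (`rcme()`): at each coarseness
scale tau = 1..80, the series is coarse-grained by non-overlapping block
means at each of the tau possible offsets; template-match counts (length
m = 4, Chebyshev distance, unordered pairs, self-matches excluded, the same
template range for m and m + 1 — the Richman–Moorman convention) are pooled
across offsets before taking `-ln(A/B)`. The tolerance R = 0.3 x SD is fixed
once per epoch from the un-coarsened signal, which makes the profile exactly
invariant to affine transforms of the input and progressively stricter in
relative terms as coarse-graining removes variance — the cause of the
characteristic decay of the profile with scale for noise-like signals.
Computing R from the epoch (the analysis unit here) rather than from a
pooled session is deliberate; a pooled tolerance can be obtained by passing
`r` explicitly. Scales where no templates match report `NA` rather than
infinity. The O(n^2) counting loop is compiled (Rcpp); one 24000-sample
epoch over all 80 scales takes on the order of 15 s on one CPU.

Refined multiscale permutation entropy (`rmpe()`): ordinal patterns of m = 4
consecutive coarse-grained samples (delay 1, ties broken by index order —
a measure-zero event for continuous signals) are tallied at every offset,
the relative frequencies averaged across offsets, and the Shannon entropy of
the averaged distribution reported in nats (maximum ln 24 ≈ 3.178;
`normalize = TRUE` divides by ln 24). Note that permutation entropy is
invariant to strictly monotone amplitude transforms exactly at tau = 1; at
coarser scales block means do not commute with nonlinear transforms, so only
linear invariance is exact.

`session_entropy()` averages per scale across a session's epochs (2–3 full
minutes in a 3-minute walk), excluding undefined scales pairwise.

## Reliability and agreement statistics

`icc_absolute()` implements the two-way random-effects, single-measure,
absolute-agreement ICC(A,1) from the ANOVA mean squares, with the F-based
95% confidence interval (Satterthwaite denominator degrees of freedom). The
consistency variant ICC(3,1) is available for sensitivity analyses
(`type = "C1"`). `icc_category()` maps poor (< 0.40), fair (0.40 to < 0.60),
good (0.60 to < 0.75), excellent (>= 0.75); the boundaries 0.60 and 0.75
belong to the higher category. `bland_altman()` uses d = a - b, limits of
agreement bias +/- 1.96 x sample SD (the conventional normal-quantile
multiplier, not a t quantile) and a two-sided paired t-test for the bias.
`cv_rms()` uses the exact two-point SD `|a - b|/sqrt(2)` per subject and
aggregates quadratically. `scale_correlations()` correlates per-subject
entropy at each scale with a reference variability measure, excluding
missing scales pairwise; across the 80 scales p-values are reported without
multiple-testing correction (matching the p <= 0.05 convention of the
analysis this package operationalizes); apply `p.adjust()` to the output if
a corrected view is wanted.

## The synthetic gait generator

`simulate_session()` draws a ground-truth stride plan and renders all three
recordings on a shared time base, with a 1.5 V square pulse on each
auxiliary channel in the last half second for synchronization testing.

* **Stride plan.** Right-stride durations follow a stationary AR(1) process
  with mean 1040 ms and SD 19.6 ms by default — the defaults are the
  population values of the cohort this chain targets (healthy adults over
  70 walking at preferred pace). `ar1_phi = 0` (white) by default since no
  temporal structure is asserted; the parameter exists to probe entropy
  sensitivity. Left heel-strikes sit half a stride after right ones plus a
  jitter of SD/4; toe-offs follow same-foot heel-strikes by a duty factor
  of 0.62 strides (within the 0.60–0.65 range typical of older-adult
  walking).
* **Force plate.** Each stance contributes an M-shaped vertical profile
  (cosine-interpolated knots peaking at 1.20 and 1.15 body weights with a
  0.72 mid-stance valley; the walk-averaged vertical force is 1.04 body
  weights, respecting impulse bookkeeping) plus a 12 ms impact transient of
  400 N starting exactly at the heel-strike, so the peak jerk marks the
  event. The first force peak sits 35 ms after the heel-strike — early
  enough that the 50 ms backward search window always reaches the transient. The
  mediolateral force is a loading-response pulse over the first half of
  stance, signed by foot.
* **Waist IMU.** Earth-frame vertical acceleration is a smooth
  step-frequency oscillation (0.12 g) plus a 0.5 g raised-cosine pulse of
  30 ms half-width at every heel-strike. The 30 ms width is deliberate:
  a much narrower pulse excites ringing of the detector's 6 Hz low-pass
  stage, creating mid-step rebound maxima near the prominence threshold —
  real waist impacts carry their energy at comparable widths. The sensor is
  tilted (default 8 degrees) with a slow 2-degree sway; the gyroscope
  carries the exact angular rate of that motion.
* **Ankle IMU.** The sagittal gyro channel has -120 deg/s troughs of 25 ms
  half-width centered exactly at each right heel-strike and toe-off, and a
  +280 deg/s swing lobe between toe-off and the next heel-strike. The swing
  (and its toe-off) preceding the first recorded heel-strike is also
  rendered — walking is ongoing before the window — because a
  swing-anchored detector cannot otherwise see the first heel-strike; by
  the same geometry the final toe-off of a window has no completed swing
  after it and is structurally undetectable.

Identical seeds give bit-identical output. What the generator does *not*
emulate: turning at track ends (continuous straight gait only), soft-tissue
artifact, sensor bias/drift and nonstationarity, left-right asymmetries
beyond timing jitter, and the force plate's finite natural frequency.
Passing detection tests on these signals therefore demonstrates the
correctness of the algorithm logic and timing, not robustness to every
artifact of real recordings.

## A worked run

```{r, eval = FALSE}
sess <- simulate_session(gait_sim_params(seed = 7))
res <- run_session(sess)            # full chain, 80 entropy scales
res$outcomes$force
res$outcomes$waist
head(res$entropy$rcme$values)
```

`run_session()` logs per-stage event counts, matches the IMU chains to the
force plate at 0.2 s (disable with `matched = FALSE` for standalone field
use — note that the waist chain's validity was established *with* the
concurrent force plate, so standalone waist outcomes carry that caveat),
median-ratio filters every stride set, and computes both entropy profiles
over 1-minute epochs. `simulate_cohort()` plus `run_reliability()` assemble
two-session test-retest studies; `chain = "plan"` computes outcomes directly
from the ground-truth plans when thousands of simulated sessions are needed
(e.g. null-distribution work), `chain = "force"` runs the full detection
chain.

## Numerical choices and limitations

* Jerk is a central difference of the raw vertical force; no pre-smoothing.
* Sync alignment uses the first upward threshold crossing (0.75 V against
  the 1.5 V pulse); sub-sample interpolation is not attempted since only a
  relative offset within one sample of the coarser device is needed.
* Parabolic refinement is clamped to its fitting half-width; degenerate
  (non-concave) fits fall back to the grid minimum.
* `rcme` on very short or very low-variance epochs can yield zero match
  counts; those scales are `NA` and session averaging skips them.
* ICC confidence intervals assume the two-way normal ANOVA model; with
  n < 10 subjects they are wide and the F-based bounds can be markedly
  asymmetric.
* Problem sizes in the test suite (30–60 s walks, 4000-sample epochs,
  reduced scale sets for unit tests; full 180 s / 80 scales in the
  acceptance checks) were chosen to exercise every code path at study-like
  signal structure.
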