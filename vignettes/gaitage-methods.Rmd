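---
title: "Estimating age from trunk-IMU gait tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age from trunk-IMU gait tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitage)
```

## The problem

Dynamic balance ability (DBA) — the capacity to control the body's centre of
mass during movement — declines with age, and its clinical surrogates, the
Timed Up and Go test (TUG) and the six-minute walk test (6MWT), are routine
in geriatric assessment. Raw instrumented readouts of these tests are hard
for a lay person to interpret; an *age* predicted from the sensor signal is
immediately interpretable. `gaitage` implements the full chain from a single
trunk-worn IMU (tri-axial accelerometer + gyroscope at 100 Hz, worn at L2)
to a predicted age: preprocessing, TUG sub-task segmentation, a 132-feature
engineering scheme, and a gradient-boosted regression of age with
feature-importance reporting.

Because no raw cohort recordings are publicly available, the package ships a
synthetic cohort generator with ground truth. Its defaults emulate the study
population the pipeline is designed for: 136 subjects aged 60–90 (36/64/36
in their 60s/70s/80s, 33 male / 103 female), three TUG trials and one 6MWT
per subject.

## Signal model of the generator

Walking acceleration is modelled as a harmonic sum. With step period
$T_{step}$ (step frequency $f_{step} = 1/T_{step}$, stride frequency
$f_{str} = f_{step}/2$), the vertical axis is

$$
a_{VT}(t) = A\left[\sin(2\pi f_{step}t)
  + \beta \sin(2\pi f_{str}t)
  + \gamma \sin(2\pi\,3 f_{str}t)\right] + \varepsilon(t),
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),
$$

where $\beta\in[0,1)$ is the left/right *asymmetry* (a stride-periodic
amplitude difference between alternating steps) and $\gamma\ge 0$ the
*roughness* (energy at a high stride harmonic). The anterior–posterior axis
mirrors this structure with phase offsets; the mediolateral axis is
stride-periodic (sway alternates side each stride) with an even-harmonic
roughness term. These choices are the minimal model in which every 6MWT
feature below responds in the physiologically expected direction:

* $\beta = 0$ makes the signal periodic at the step frequency, so step and
  stride regularity coincide and the symmetry index is 0; increasing
  $\beta$ strictly lowers step regularity.
* increasing $\gamma$ strictly lowers the harmonic ratio of the vertical
  axis and raises approximate entropy.

The roughness harmonics sit at the 3rd stride harmonic (vertical/AP) and
2nd (mediolateral). This placement is deliberate: the 6MWT low-pass filter
(below) has an effective cutoff near 1.7 Hz at 100 Hz sampling, and
harmonics beyond ~4 Hz would be annihilated by faithful preprocessing,
leaving the smoothness parameter without observable effect.

TUG trials consist of two pitch half-sine pulses (chair transfers, default
width 1.5 s) and two yaw half-sine pulses (turns, default width 2.0 s) in
chair–turn–turn–chair order, with gait acceleration filling the two 3 m
walking phases (duration 3 m / gait speed). Pulse signs are drawn at random
because turn direction is unconstrained in the protocol; rectification
before detection makes the analysis sign-free. Ground-truth sub-task
intervals are the analytic threshold crossings of the clean pulses at the
default 25/32 deg/s thresholds; gait phases are the gaps between them.

The default age coupling maps age linearly onto every parameter in the
direction reported for ageing gait (slower steps and walking, more
asymmetry, less smoothness, weaker turns); `planted_age_coupling()` drives
only walking pace and turn angular velocity, producing a cohort whose age
signal is identifiable and deliberately split across the two tests. The
magnitudes are configuration, not claims: they were chosen once to give a
realistic elderly range (step time 0.50–0.65 s, gait speed 1.25–0.89 m/s,
turn peaks 95–77 deg/s) with 5 % log-normal subject-level jitter, and the
amplitudes (≈0.8–1.8 m/s²) match trunk-worn accelerometry magnitudes.

What the generator does *not* emulate: soft-tissue and sensor-mounting
artifacts, gravity offset and orientation drift, turnarounds within the
6MWT course, fatigue drift over the six minutes, aborted or irregular TUG
trials, and any nonlinear or non-monotone age physiology. Tests passing on
this generator therefore validate the *computational* chain — segmentation
recovers constructed events, features respond to planted parameters, the
model recovers a planted age signal — not clinical accuracy on real
cohorts.

## Preprocessing

Filters are specified as (passband edge, steepness, stopband attenuation),
the way MATLAB's `lowpass()` takes them: the stopband edge is
`passband + (1 − steepness) × (Nyquist − passband)`. We design the
minimal-order Butterworth meeting 3 dB at the passband edge and the stated
attenuation at the stopband edge, place the cutoff so the stopband
constraint is met exactly, and apply it forward–backward (zero phase) so
that event boundaries are not delayed. Defaults: TUG 0.01 π/sample,
steepness 0.83, 60 dB (≈ 0.5 Hz edge at 100 Hz); 6MWT 0.02 π/sample, 0.86,
40 dB (≈ 1 Hz edge). The TUG passband is aggressive for gait-band content —
at 100 Hz it keeps only sub-0.9 Hz energy — but is retained as the protocol
default; both specs are ordinary arguments (`filter_spec()`) wherever they
are used. Zero-phase filtering has edge transients over roughly the first
and last second of a record; step detection and regularity statistics are
dominated by the ~360 s interior, but the first/last detected step may
shift by a few tens of milliseconds.

The resultant acceleration is the per-sample Euclidean norm of the three
filtered axes. Note that squaring makes the resultant step-periodic even
though the mediolateral axis is stride-periodic, which is why the resultant
is a valid axis for step/stride regularity.

## TUG segmentation and features

Pitch and yaw are rectified, filtered, and thresholded at 25 and 32 deg/s.
Maximal supra-threshold runs are merged across gaps shorter than 0.3 s and
runs shorter than 0.3 s are discarded (de-bouncing the method needs but the
protocol does not specify; both knobs are in `threshold_spec()`). A valid
trial must produce exactly two chair and two turn events in
chair–turn–turn–chair order; anything else raises a segmentation error
reporting the counts found, signalling an atypical trial rather than
guessing. Event boundaries are the first/last samples of the thresholded
run — the plainest reading of threshold-based detection; rectify-then-filter
is the default order (configurable), matching detection on a smoothed
magnitude envelope.

The six sub-tasks give six timing features (total time; the four chair/turn
durations; gait time as the mean of forward and backward gait) and
rms/min/max of seven filtered signals (three acceleration axes, resultant,
yaw/pitch/roll) over five groups, with forward and backward gait averaged
*at the feature level*: 6 + 3 × 7 × 5 = 111. Per subject, the three trials'
feature vectors are averaged (`aggregate_trials()`); treating trials as
independent rows is possible by skipping aggregation, but averaging is the
default because the cohort's age label is per subject and subject-level
splitting would otherwise be mandatory for every downstream user.

## 6MWT features

Steps are local maxima of filtered vertical acceleration above an adaptive
threshold (25 % of the de-meaned maximum, minimum inter-peak distance
0.35 s); the adaptive fraction keeps the weaker of two alternating peaks
detectable under asymmetry. The six gait parameters follow from the step
train, with stride length estimated from stature as 0.83 × height (a step
is ≈ 0.415 stature) — the constant is exposed as `k_height`.

Step and stride regularity come from the unbiased autocorrelation
$A(m) = \frac{1}{N-m}\sum_i x_i x_{i+m}$ computed on the mean-removed
signal and normalized by $A(0)$ — mean removal and normalization are what
make the coefficients correlation-like, bounded by 1 and comparable across
subjects. SR is the highest local maximum of $A$ within a step-lag window
and STR within a stride-lag window. The extractor centres these windows on
the measured step time (0.7–1.3× for SR, 1.6–2.6× for STR) because fixed
windows fail for slow elderly gait: with a 0.6 s step the stride lag falls
inside any window wide enough to catch fast steppers, and a first-peak rule
latches onto harmonic ripples on the resultant axis. The symmetry index is
$(SR - STR)/\max(SR, STR)$.

The harmonic ratio uses discrete Fourier magnitudes at integer multiples of
the stride frequency over consecutive non-overlapping windows of exactly
ten strides (the window choice makes the stride harmonics exact FFT bins),
20 harmonics by default, averaged across windows. Vertical and AP axes use
even/odd (step-periodic content is even with respect to the stride); the
mediolateral axis uses odd/even. A vanishing denominator returns a capped
sentinel (default 1000) rather than infinity.

Approximate entropy is Pincus' $\Phi^m(r) - \Phi^{m+1}(r)$ with Chebyshev
distance and self-matches, $m = 2$, $r = 0.2\,\mathrm{SD}$ of the whole
record. The quadratic cost on a 36 000-sample walk is bounded by computing
it on consecutive 30 s epochs and averaging; the kernel (Rcpp) counts
template matches along diagonals with a run-length scan, giving both
$\Phi^m$ and $\Phi^{m+1}$ in one $O(N^2)$ pass. A pure-R double-loop
implementation of Pincus' definition serves as the oracle in the test
suite.

Census: 6 gait parameters + SR, STR, SI on {VT, AP, resultant} + HR and
ApEn on {VT, ML, AP} = 21.

## Age regression

The subjects-by-features table is split at subject level 70/10/20
(train/validation/test) with largest-remainder rounding — 136 subjects give
95/14/27 — deterministically per seed. XGBoost hyperparameters (learning
rate 0.01–0.3 log-scale, depth 2–8, 50–600 rounds, row/column subsampling
0.5–1, L2 0–10) are tuned by sequential model-based search: a Latin
hypercube initial design that always includes the library defaults, then
expected-improvement acquisition under a Gaussian-process surrogate,
minimizing validation MAE. The test set is fingerprinted at split time and
re-checked before evaluation, so leakage is structurally impossible. The
final model is refit on the training set with the tuned hyperparameters and
evaluated once: MAE in years, MAPE in percent (absolute values throughout).
Feature importance is XGBoost gain, normalized over *all* input features to
sum to 1 (unused and zero-variance features score 0).

`compare_feature_sets()` runs the identical protocol on the TUG-only (OT,
111 features), 6MWT-only (OS, 21) and pooled (AG, 132) sets and reports
per-set MAE/MAPE plus their across-set mean ± SD. On the default planted
cohort, pooling is expected to match or beat the better single test —
checked as a median over ten split seeds because single splits of 27 test
subjects are noisy.

## Numerical and scale choices

* Problem sizes: the acceptance checks and the bundled experiments use the
  full 136-subject cohort with 360 s walks; module-level tests use 10–30
  subject cohorts and 20–120 s walks, which exercise identical code paths.
  Tuning budgets of 6–10 trials are used in the multi-seed experiments and
  50 is the single-model default.
* Seeds: every stochastic step (cohort draw, subject jitter, split, search,
  boosting) is driven by an explicit integer seed; identical inputs and
  seeds reproduce results bit-for-bit.
* Degenerate inputs fail loudly with classed errors: empty series, constant
  labels, sub-threshold pulse requests, wrong event counts, fewer than two
  steps, zero-variance autocorrelation.
* Ties: largest-remainder rounding breaks ties in listed order
  (train, validation, test); equal-height autocorrelation peaks resolve to
  the smaller lag.

## Known limitations

The generator's linear, monotone age coupling makes age recovery easier
than on real cohorts; reported MAE/MAPE on synthetic cohorts characterize
the pipeline, not clinical performance. Segmentation handles exactly the
canonical chair–turn–turn–chair trial and deliberately refuses pathological
trials. The 6MWT turnarounds of a real 30 m course are not modelled and no
exclusion rule is applied around them. Gender-stratified modelling is out
of scope.
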