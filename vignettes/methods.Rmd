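---
title: "From wearable sensor traces to heading-bias statistics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable sensor traces to heading-bias statistics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdrift)
```

## The scientific problem

When people walk "straight ahead" without vision, their heading drifts.
After lying for several minutes on one side, the internal estimate of the
direction of gravity is biased toward the recently held body orientation,
and this bias is expected to pull blindfolded walking toward the adaptation
side: leftward after left-ear-down (LED) lying, rightward after
right-ear-down (RED), relative to supine and to a sitting baseline.

`gaitdrift` implements the complete measurement-to-inference pipeline for
this paradigm with two wearable systems recorded at 100 Hz:

* a chest IMU (3-axis gyroscope + accelerometer) from which the heading
  (yaw) trajectory is estimated, and
* pressure-sensing shoe insoles (16 sensors each, plus an embedded IMU)
  from which the lateral weight distribution between the feet is derived.

Two measures summarize each *walking segment* (WS) — a stretch of
continuous walking between experimenter-imposed turns:

* **yaw slope** (deg/s): the ordinary least-squares slope of the unwrapped
  chest yaw against time within the WS; positive = turning left;
* **CoP symmetry**: the left foot's mean stance-phase lateral-medial
  centre of pressure minus the right foot's, in insole-normalized units
  (both feet expressed with medial positive); negative = weight shifted
  left.

Because no public recordings exist for this paradigm, the package ships a
synthetic-trial generator with exact ground truth, and all validation is by
parameter recovery.

## Pipeline stages

### Synchronization

The two systems run on independent clocks. Each trial starts with a
deliberate leg slap that produces a dominant medio-lateral acceleration
transient in the left ankle IMU and the left insole. `detect_slap()` finds
the largest absolute ML-acceleration peak above a threshold; the default
threshold is 10 x the median absolute deviation of the searched signal, a
scale-free rule chosen because the slap is, by protocol, an order of
magnitude above walking accelerations. If no peak exceeds the threshold the
trial is reported as unusable rather than silently mis-aligned. When
several samples exceed the threshold the global maximum wins.
`synchronize()` then shifts the insole clock by the difference of the two
slap times; values are never resampled, and shifts accumulate against the
original time vector so that a net-zero shift restores the original
timestamps bit for bit. No clock-skew (drift-rate) estimation is performed;
as in the measurement protocol, each system's gait events are detected on
its own clock, which makes slow inter-system drift harmless.

### Missing-sample repair

Short dropouts are reconstructed per channel with modified Akima cubic
Hermite interpolation, a shape-preserving piecewise cubic whose endpoint
slopes are weighted averages of neighbouring secant slopes
(weights `|d1 - d2| + |d1 + d2| / 2`). It reproduces linear signals exactly
and does not overshoot between support points. Gaps longer than
`max_gap_s` (default 0.2 s — interpolating across a substantial fraction of
a stride would fabricate gait structure) and gaps touching a trace boundary
are left missing and reported. Observed samples are never modified.

### Gait events and walking segments

Event detection runs on the sagittal-plane (medio-lateral axis) angular
velocity of each ankle (IMU system) and of each insole's embedded gyro
(insole system), smoothed by a zero-phase fourth-order Butterworth low-pass
at 12 Hz. Zero-phase (forward-backward) filtering is used so event
timestamps are not lagged; the implementation pads with odd reflection and
steady-state initial conditions so that edge transients do not distort
events near trace boundaries.

Per stride, three events are detected in order: the **mid-swing** positive
peak (local maxima above an adaptive threshold of 0.4 x the 95th percentile
of the signal's positive part, with a 0.4 s minimum separation — a
physiologic cadence bound), the **toe-off** valley (minimum within at most
0.8 s before the peak, not crossing the previous peak), and the **heel
strike** (first non-positive sample after the peak). Strides missing an
event are dropped and counted. The threshold quantile rule is this
package's documented stand-in for per-trial manual thresholding; it is
scale-free, so gyro gain differences between devices do not matter.

Mid-swing times of both feet are merged and split into walking segments
wherever consecutive strides are at least 2 s apart (turns take longer than
2 s). Segments with fewer than 3 strides are discarded: steps at segment
boundaries are highly variable and a regression over a couple of strides is
meaningless.

### Orientation and yaw slope

`fuse()` integrates the chest gyroscope into an attitude quaternion and
applies a small complementary correction that rotates the tilt components
toward the accelerometer's gravity direction. The correction axis is
perpendicular to gravity, so the accelerometer can never influence yaw;
with no magnetometer, yaw is pure gyro integration from the identity
orientation (sensors are zeroed in a neutral standing pose). The tilt
correction time constant defaults to 1 s, which pulls a 30 degree initial
tilt error below half a degree within 5 s while leaving walking-frequency
content essentially untouched. Euler angles use the intrinsic
yaw-pitch-roll (cranio-caudal, medio-lateral, anterior-posterior) sequence;
walking keeps pitch far from the gimbal-lock singularity, which is treated
as an error rather than handled specially.

`yaw_slope()` unwraps the yaw across +/-180 degree jumps and fits ordinary
least squares over all samples of the WS (not per-stride means): the twist
oscillation superimposed by upper-body rotation averages out over the
segment except for a spectral-leakage term whose closed form,
`-12 A cos(phi) / (omega L^2)` for amplitude `A`, angular frequency
`omega`, phase `phi` and segment length `L`, is below 0.04 deg/s for a
10 degree, 0.9 Hz oscillation over a 24 s segment. This term, not sensor
noise, dominates the recovery error budget, which is why the validation
criterion is stated as a median over trials with randomized oscillation
phase.

### Centre-of-pressure symmetry

The insole sensors are modelled as a 4 x 4 grid of cell centers spanning
the normalized insole plane (-0.5..0.5 on both axes; the real device
specifies the sensor count but not coordinates). The per-sample CoP is the
pressure-weighted centroid of sensor positions and therefore always lies in
the convex hull of the active sensors. A step's stance phase runs from a
foot's heel strike to that foot's next toe-off; within it, samples with
total force above 5% of the trace's 95th-percentile force are averaged
force-weighted. Step values are then averaged unweighted per WS (two-stage
averaging: weighted within a step, plain across steps).

The two insoles' lateral axes are mirror images in device coordinates. The
package fixes one anatomical convention — positive = medial on both feet,
the right foot's axis being flipped at computation time — so that the
symmetry `cop_sym = left - right` is a pure left-minus-right contrast with
the sign contract: leftward disequilibrium negative, rightward positive.
This convention is a deliberate design choice of the package and is
documented rather than inferred, because device-frame descriptions of the
lateral axis are ambiguous between sources.

### Study-level inference

The first three WS of each trial enter a long-format study table
(participant, condition, repetition, WS, measure, value). Per
condition x WS cell, points farther than 3 x IQR beyond the quartiles are
removed (boundary-exact points retained; the filter is idempotent because
fences are computed once per input group).

Each measure is modelled as

```
value ~ trial * walkingSegment,  random = ~ 1 | participant / walkingSegment
```

fitted with `nlme::lme`: fixed effects for condition, segment and their
interaction (adaptation effects may decay across segments), random
intercepts for participant and for segment-within-participant (the decay
speed differs between subjects). Estimated marginal means per
condition x WS and all six pairwise condition contrasts per WS are computed
with `emmeans`, Tukey-adjusted; degrees of freedom use the containment
method, which is recorded in every model object. Singular fits (a variance
component collapsing to zero, which legitimately happens on synthetic data
generated without a WS-level random effect) are reported with a warning and
the component is kept at zero rather than aborting.

For the yaw-CoP correlation, WS1 values are averaged over the repetitions
of each condition per subject, the subject's baseline average is
subtracted, and the Pearson correlation is computed over the resulting
three points per subject (supine, RED, LED) for each measure. Averaging
before subtracting (rather than subtracting per repetition) follows the
two-step description of the procedure this package implements; with
balanced repetitions the two orders give identical points.

## The synthetic-data generator

`simulate_trial()` produces the five traces of one trial plus exact labels.
Its defaults are the study conditions: 100 Hz sampling, 2 minutes of
walking split into 5 segments (matching the reported ~4.5 segments per
2-minute walk) separated by >= 2 s turn gaps, a leg slap at 2.5 s, and four
conditions (baseline, supine, RED, LED).

* **Ankle angular velocity** is a sum of three Gaussian lobes per stride —
  toe-off valley (-100 deg/s), mid-swing peak (+300 deg/s, typical of
  comfortable walking), and a landing lobe whose amplitude is solved so the
  analytic waveform crosses zero exactly at the heel-strike time with
  finite slope. Event times are therefore exact oracle labels, which is the
  reason for choosing analytic bumps over biomechanically fitted curves.
* **Chest signals** encode yaw(t) = integrated drift + twist oscillation
  (default 10 degrees at 0.9 Hz with per-trial random phase, since real
  twist phase is arbitrary), pitch = roll = 0; the accelerometer carries
  gravity rotated by the instantaneous orientation plus white noise, with
  no linear walking acceleration — the pipeline uses the accelerometer only
  for tilt correction. The true per-WS slope is the OLS slope of the
  drift-only component over the segment's samples.
* **Drift decay** across the walk is available as an exponential with
  configurable time constant but is off by default: the decay's functional
  form is not established for this paradigm, so the default study-level
  simulations leave the interaction term null.
* **Insole pressure** realizes a heel-to-toe CoP ramp during each stance
  with total force following a half-sine, distributed onto the 4 x 4 grid
  by bilinear weights (which reproduce the target centroid exactly). The
  configured lateral offset is split +/- half per foot with opposite signs,
  so the true `cop_sym` equals the configured value exactly.
* **Condition defaults** are baseline +0.1, supine +0.2, RED -0.4,
  LED +0.6 deg/s of drift — the ordering LED > supine > baseline > RED with
  a small overall leftward bias — and CoP offsets 0, 0, +0.05, -0.05, i.e.
  opposite in sign to the heading drift, so the study-level correlation is
  negative by construction. Real effect sizes are not published as numbers;
  these values were chosen once as plausible magnitudes and are not tuned.
* The slap impulse is 10 x the maximum walking ML acceleration,
  guaranteeing separability as in the real protocol.

`simulate_study()` adds per-subject persistent heading biases (sd
0.2 deg/s), per-trial drift jitter (sd 0.2 deg/s) and CoP jitter (sd 0.01),
and randomizes condition order per subject; everything is a pure function
of the seed. `simulate_measures_study()` draws the per-segment measures
directly from the same mixed-effects structure without generating traces;
it is used for inference-layer calibration (type-I error, power,
correlation direction), where hundreds of replicate studies are needed and
raw-trace simulation would add runtime without adding information.

### What the generator does not emulate

Real recordings contain soft-tissue artifacts, sensor bias instability and
temperature drift, inter-subject waveform variability, double-support
asymmetries, turning kinematics inside the gaps, and foot-shape-dependent
insole coverage. Passing recovery tests on this generator therefore
demonstrates the correctness of the pipeline's algorithms under the stated
signal model, not field performance on arbitrary hardware.

## Numerical choices and degenerate inputs

* Indices are 0-based and windows half-open throughout the event and
  segment layer; event times in seconds always come from the trace clock.
* The adaptive mid-swing threshold returns an empty event set on flat
  signals; downstream stages treat empty segments as missing values, never
  as zeros.
* An all-zero pressure frame (swing) has undefined CoP and is excluded by
  the contact threshold rather than contributing a spurious origin point.
* A single step in a WS reports sd 0 by convention; a WS with no valid
  step reports missing values and the trial is excluded from CoP analyses
  only (yaw is unaffected), mirroring how single-system data loss is
  handled in practice.
* Quaternions are renormalized after every update; Euler extraction
  errors out near |pitch| = 90 degrees instead of returning garbage.
* Zero-norm accelerometer samples are skipped by the tilt correction
  (gyro-only step).

## Validation problem sizes

The test suite and the acceptance script validate with: noise-free
event-exactness on a full 2-minute trial; stride recall at 10% gyro noise
over 100 (suite) / 50 (script) seeded 60 s trials; segment counts for 1-6
segments; a drift grid of {-1, -0.5, 0, 0.5, 1} deg/s x 20 (suite) / 10
(script) seeds on 100 s walks; CoP offsets {0, +/-0.05, +/-0.1} x 20/10
seeds on 40 s walks; 50 random clock offsets in +/-30 s; 100 replicate
studies for LED-RED power and 200 for the null rejection rate; and 20
studies for the correlation direction. These sizes were chosen to give
stable pass/fail behaviour at interactive runtimes and are documented here
as the package's own simulation conventions.

## Known limitations

* Yaw is unobservable from gravity: any gyro x-axis bias integrates into a
  spurious drift indistinguishable from real heading drift. The paradigm
  addresses this with baseline trials and within-subject contrasts, not the
  filter.
* The per-trial threshold rule, stance definition, insole geometry and the
  anatomical lateral-axis convention are documented package choices where
  the measurement protocol is underspecified; results depending on them
  (notably absolute CoP values) should be compared across conditions, not
  across devices.
* The containment degrees of freedom for mixed-model contrasts are one of
  several defensible approximations; the inference layer is validated by
  simulation calibration, not by exact small-sample p-values.
* No path integration or absolute position is attempted; yaw slope is a
  rate-of-turning proxy for heading deviation.
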