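---
title: "Methods: IMU gait analysis for the six-minute walk test"
author: "imugait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU gait analysis for the six-minute walk test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The measurement problem

People with knee osteoarthritis walk with a slowed and flattened gait. A
six-minute walk test (6MWT) on a straight, level 32-m course, recorded with
three wearable inertial measurement units — one on each shank at the tibial
tuberosity and one on the sacrum — captures this objectively and outside a
laboratory. Each sensor streams tri-axial accelerometer (±16 g), gyroscope
(±2000 °/s) and magnetometer (±8 Gauss) data, at 60 Hz in real-time mode
(120 Hz logging is also accepted).

`imugait` implements the complete chain from those raw streams to clinically
reportable quantities: segment orientation in the three anatomical planes,
gait cycles per limb, 6MWT metrics (steps, distance, average step length,
speed), per-minute angle snapshots, and the test–retest reliability of those
snapshots (Cronbach's $\alpha$ and the one-way intraclass correlation
coefficient). Because clinical recordings of this kind are rarely shareable,
the package also contains a forward simulator that generates the sensor
streams *with known ground truth*; every processing stage is validated
against it.

## Orientation estimation

Each sensor's orientation is tracked as a unit quaternion $q_k$ (body to
world) by strap-down integration: the bias-corrected angular rate
$\boldsymbol\omega_k$ is applied as an exact axis–angle increment over each
sampling interval,
$$q_{k+1} = q_k \otimes \exp\!\left(\tfrac{1}{2}\,\boldsymbol\omega_k\,
\Delta t\right),$$
which is exact for piecewise-constant rotation. Gyroscope integration alone
drifts, so each update is followed by a small complementary correction:

* **Tilt**: the estimate is rotated a fraction `accel_weight` (default 0.02
  per update) of the way toward agreement with the measured specific-force
  direction, but only when $\lvert\,\|\mathbf a\| - 1\,\rvert < 0.1$ g, so
  stride impacts do not masquerade as gravity.
* **Heading**: the horizontal angle between the measured magnetic field
  (rotated into the world frame) and the calibration-window reference field
  is reduced by a fraction `mag_weight` (default 0.01 per update).

At 60 Hz these defaults give time constants of roughly 0.8 s (tilt) and
1.7 s (heading). The heading gain is deliberately the faster of the
conventional choices: tilt corrections leave a second-order heading residual
(correcting a 5° tilt error by rotating about the gravity-error axis leaves
a heading error of order $\theta^2/2 \approx 0.2°$), and with
`mag_weight = 0.01` a 5° static misalignment of *any* axis decays below
0.1° within 10 s, which we adopt as the package's convergence requirement.

Angular rate, accelerometer and magnetometer channels are pre-filtered with
a zero-phase (forward–backward) 4th-order Butterworth low-pass, default
cutoff 6 Hz: the energy of human gait lies below about 5 Hz, and zero phase
matters because cycle events are read off the filtered signals. The
forward–backward pass is applied over an odd-reflection padding of about
three time constants so that its start-up transient does not leak into the
standing calibration window; a constant input is reproduced exactly (DC
gain 1).

### Calibration and zero-referencing

The test begins with 5 s of quiet standing. From this window the package
estimates, per sensor, (i) the gyroscope bias (mean rate), (ii) the
reference orientation by the two-vector (TRIAD) construction — gravity
fixes the tilt, the horizontal magnetic field fixes the heading — and
(iii) the magnetic reference field. Euler angles are reported relative to
this standing reference so that the habitual posture reads 0° in every
plane, with one exception: **pelvic tilt** (the sacrum's sagittal angle) is
reported as an absolute angle, because the forward inclination of the
pelvis is itself the quantity of clinical interest (typical values near
21.5° in this population).

Angles use the intrinsic Z–Y′–X″ (yaw–pitch–roll) sequence with the plane
mapping sagittal = pitch, frontal = roll, transverse = yaw; negative roll
and yaw denote leftward rotation. Zero-referencing subtracts the reference
angles *per plane* rather than composing relative quaternions: with yaw as
the outermost rotation this makes the sagittal and frontal angles invariant
to walking direction, so the 180° course turns do not flip their sign —
relative-quaternion referencing was measured to distort the sagittal
profiles by several degrees at each turn, which settled the design choice.
Zero-referencing records itself on the series object and is idempotent.

## Gait segmentation

**Activity classification.** The recording is cut into 1-s windows; the RMS
magnitude of the pooled shank gyroscopes labels each window static
(< 10 °/s), dynamic (> 30 °/s) or unidentified (between), and same-label
neighbours are merged. Unidentified intervals are excluded from locomotion
analysis. The thresholds are package defaults chosen to separate quiet
standing (noise-level rates) from walking (peak shank rates of 50–300 °/s)
with a wide guard band; they are configurable.

**Initial contact.** Within dynamic segments, an initial contact is the
negative-going zero crossing of the shank's sagittal angular velocity that
follows the mid-swing velocity peak — a standard single-shank-IMU event
heuristic. Candidate crossings must be preceded by a swing peak of at least
30 % of the robust (95th-percentile) positive velocity, and events closer
than 0.35 s are pruned, keeping the stronger swing. Crossing times are
interpolated below the sampling interval. Dynamic segments are padded by
one classification window so an event on a segment edge is not lost to
window quantization.

**Pairing and quality.** Accepted cycles from both limbs are merged in time
order and paired by sequential alternation: each pair is a maximal run of
two consecutive opposite-limb cycles. This rule is symmetric in the limbs
and well defined when one limb misses a stride (the unpartnered cycle is
skipped). Perfect alternation makes "the overlapping cycle" ambiguous —
each right cycle overlaps two left cycles by half a stride — which is why
pairing is defined on the merged sequence instead. A pair is rejected when
either cycle's duration deviates more than 30 % from the session median or
its sagittal range of motion is below 5°; rejections carry their reason.
The initiating limb of a pair is the earlier contact, cross-checked against
pelvic axial rotation (locally detrended after unwrapping): its positive
excursion coincides with left contact. Disagreement or a flat excursion
(< 0.5°) sets an ambiguity flag.

**Normalization.** Each cycle's angle trace is linearly interpolated onto
101 points spanning 0–100 % of its duration; profiles report the pointwise
mean and ($n-1$)-denominator SD. Normalization is invariant to uniform time
warping up to interpolation error.

## 6MWT metrics

Distance is derived from the course geometry, not from double-integrated
acceleration (which drifts): each detected 180° turn — a cumulative
excursion of the smoothed, unwrapped pelvic heading — completes one 32-m
straight, and the partial final straight is estimated from time at the
session's pace (straight length × time since the last turn ÷ mean
per-straight traversal time). A step-count-based partial estimate was
rejected: pairing consumes edge events at the walk end and biased it by
about 2 m. Steps are twice the accepted pairs, plus one for an accepted
terminal unpaired cycle. Speed uses the full 360-s test duration, per field
convention. With no completed straight the course distance is unknown and
reported as 0 with zero-guarded derived quantities.

Per-minute snapshots, the inputs to the reliability analysis, average each
plane/placement angle over the first dynamic, turn-free interval of at
least 5 s beginning at or after minutes 1, 3 and 6 (minute boundaries
counted from the first dynamic segment; ±2 s around each turn is excluded).

## Reliability statistics

For each of the nine parameters (three planes × left leg, right leg,
pelvis), the subjects' minute-1/3/6 snapshot values form an $n \times k$
matrix ($k = 3$; subjects missing a minute are dropped listwise, with the
count reported). The package computes:

$$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_{i=1}^{k} s_i^2}{s_c^2}\right),
\qquad
\mathrm{ICC} = \frac{MS_b - MS_w}{MS_b + (k-1)\,MS_w},$$

where $s_i^2$ are the item variances, $s_c^2$ the variance of per-subject
totals, and $MS_b$, $MS_w$ the between/within-subject mean squares of the
one-way ANOVA with subjects as the random factor ($n-1$ and $n(k-1)$
degrees of freedom). This ICC is the one-way single-measure form ICC(1,1);
no two-way model is offered for the headline table because the printed
formula *is* the one-way form. Qualitative bands follow the standard
reliability conventions — ICC: poor < 0.5 ≤ moderate < 0.75 ≤ good <
0.90 ≤ excellent; $\alpha$: good = [0.8, 0.9), excellent ≥ 0.9, with lower
bands (acceptable, questionable, poor) defined below 0.8. Boundaries are
inclusive toward the higher band, the convention under which the
instrument's published validation coefficients reproduce their reported
band counts (3 moderate / 1 good / 5 excellent for ICC; 3 good /
6 excellent for $\alpha$). Cohen's $d$ (pooled-SD standardized mean
difference) is provided for group contrasts; the routine nonparametric
battery around it (Mann–Whitney, Spearman, repeated-measures ANOVA) is
deliberately left to base R's standard functions rather than re-implemented.

`reliability()` is the fitting interface: it takes the repeated-measures
matrix and returns a classed fit with `print()`, `summary()` and `coef()`
methods; `reliability_table()` assembles the nine-row table.

## The synthetic-gait simulator

The simulator is the package's source of ground truth, emulating the study
conditions rather than any particular patient:

* **Stride kinematics.** The shank sagittal angle follows a smooth
  two-harmonic template per stride, $\theta(\phi) = a_1\cos 2\pi\phi +
  a_2\cos 4\pi\phi$ with $a_2 = 0.15\,a_1$, scaled so the peak-to-peak
  excursion equals the configured ROM (default 20°, control-like; the
  research-like preset uses 14°, a flattened gait). This shape has exactly
  one negative-going velocity zero crossing per stride — at integer phase,
  the simulated initial contact — so detector and ground truth refer to the
  same event. Published numeric gait curves for this instrument are not
  available, so the template is a modelling choice: smooth, analytically
  known, and ground-truth-exact, which is what validating the pipeline
  requires. Pelvic yaw oscillates at stride frequency (±5°) with its
  positive excursion at left contact; pelvic tilt is constant at 21.5° (the
  population-typical value) plus a ±0.8° step-frequency ripple; small
  frontal/transverse shank oscillations (2°/3°) complete the three-plane
  signal.
* **Course and cadence.** Defaults emulate the control-group conditions:
  cadence 595/6 ≈ 99.2 steps/min and 0.6-m steps for 360 s — 595 steps and
  357 m on the 32-m course. Each crossing of a course length inserts a
  2-s smooth 180° heading ramp. Cadence is held constant through turns:
  slowing during turns would break the defining consistency between
  configured cadence and ground-truth step count (round(cadence ×
  duration/60), matched within ±1 by the detector), and that consistency is
  the more valuable test property.
* **Sensor model.** The accelerometer reads gravity rotated into the body
  frame plus a stride-periodic vertical bob (default 0.02 g) while walking;
  the magnetometer reads a fixed mid-latitude field (0.22, 0, −0.41) Gauss
  rotated into the body frame; the gyroscope reports the exact per-interval
  body-frame rotation increment divided by $\Delta t$ — what strap-down
  hardware outputs — so integrating the emitted gyro reproduces the true
  orientation to floating-point accuracy (instantaneous-rate sampling was
  measured to leave ~0.8° of quadrature error over 6 min and was therefore
  rejected). Optional additive white Gaussian noise per channel and a
  constant gyro bias complete the model. All randomness flows from one
  seed; identical seeds give bit-identical sessions.
* **What it does not model.** Soft-tissue artifact, 1/f sensor noise,
  quantization, magnetic disturbances, pathological event signatures beyond
  ROM/cadence scaling, or musculoskeletal dynamics. Passing the simulator
  therefore demonstrates algorithmic correctness under the stated signal
  model, not clinical validity on real patients.

`simulate_cohort()` adds a subject level: gait parameters drawn from
control-like or research-like group distributions (between-subject SDs:
cadence 7 steps/min, step length 0.05 m, ROM 2.5°, pelvic tilt 7.9°), and
per-minute snapshot angles drawn from the one-way random-effects model
$x_{sm} = \mu + b_s + e_{sm}$ with $\mathrm{Var}(b_s) = \rho\sigma^2$,
$\mathrm{Var}(e_{sm}) = (1-\rho)\sigma^2$, so the population ICC of the
downstream reliability analysis equals the configured $\rho$ exactly.

## Numerical choices and edge cases

* Quaternions are renormalized every update; deviation from unit norm never
  exceeds $10^{-6}$.
* Time windows are half-open $[t_0, t_1)$ everywhere, so adjacent windows
  partition a stream without duplicating samples.
* Cycle-detection thresholds adapt to the session (fraction of the robust
  velocity maximum) rather than absolute values, so low-ROM gait remains
  detectable.
* Degenerate inputs fail loudly and specifically: range-violating CSV rows
  are named, a dynamic calibration window is a precondition error, an
  all-constant reliability matrix is an undefined-ICC error, a zero pooled
  SD is an undefined-$d$ error. Fewer than two detectable strides is a
  diagnosable empty result, not an exception.
* Gimbal proximity is not an issue for gait (pitch stays far from ±90°);
  the Euler extraction clamps its `asin` argument defensively.
* Scale-factor and axis-misalignment corrections are accepted as identity
  (the simulator emits ideal axes); hooks exist in the calibration state.
  Magnetic-field mapping for disturbed environments is treated as an
  upstream, instrument-level concern.

## Problem sizes used in the tests

The bundled validation runs use a 60-s walk for unit-level checks and the
full 360-s test for the end-to-end and noise-robustness checks (one session
each, ~22,000 samples per sensor); reliability parameter recovery uses 500
replicates of 25 × 3 matrices per target ICC and cohorts of 200 subjects at
the snapshot level. These sizes give stable statistics while keeping the
whole suite fast enough to run routinely.

## Known limitations

Distance requires at least one completed straight; shorter walks report
zero course distance. The initiating-limb confidence flag, not the label,
degrades when turns fall inside a pair's detrending window. Reliability
confidence intervals (F-based) and two-way ICC models are out of scope, as
are Bland–Altman analysis, running gait, stair/turn sub-classification and
position tracking.
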