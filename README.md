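# imugait

Gait analysis for the six-minute walk test (6MWT) from three body-worn
inertial measurement units — one on each shank and one on the sacrum — aimed
at objective gait assessment in populations such as women with advanced knee
osteoarthritis, where walking is typically slowed and flattened and
laboratory gait analysis is impractical.

The package implements the full chain from raw 9-DOF sensor streams
(tri-axial accelerometer ±16 g, gyroscope ±2000 °/s, magnetometer ±8 Gauss,
60 or 120 Hz) to reportable quantities:

* **Orientation**: quaternion strap-down integration
  $q_{k+1} = q_k \otimes \exp(\tfrac12\,\omega_k\,\Delta t)$ with
  complementary accelerometer/magnetometer drift correction, zero-phase
  Butterworth pre-filtering, 5-s standing calibration and zero-referencing
  (pelvic tilt stays absolute).
* **Gait segmentation**: static/dynamic/unidentified activity
  classification, per-limb initial-contact detection from the shank
  sagittal angular-velocity signature, left–right cycle pairing with
  quality rejection, and 0–100 % normalized mean ± SD angle profiles in the
  sagittal, frontal and transverse planes.
* **6MWT metrics**: steps, course-based distance (turn counting on the
  32-m straight, not drifting double integration), average step length,
  speed, and per-minute angle snapshots at minutes 1, 3 and 6.
* **Reliability**: Cronbach's
  α = k/(k−1) · (1 − Σsᵢ²/s_c²) and the one-way single-measure
  ICC = (MS_b − MS_w)/(MS_b + (k−1)·MS_w) over the minute-1/3/6 snapshots,
  with standard qualitative banding, plus Cohen's *d*.
* **Synthetic gait**: a forward simulator of complete 6MWT sessions with
  exact ground truth (contact times, step count, turns, distance, angle
  profiles), so every stage is testable without clinical recordings.

## Worked example

Simulate a control-group-like 6MWT (99.2 steps/min, 0.6-m steps, 32-m
course, 21.5° pelvic tilt) and run the full pipeline:

```r
library(imugait)

sim <- simulate_session(gait_sim_config(duration_s = 360, seed = 1))
sim
#> <gait_simulation> 595 steps over 360 s (11 turns, 357 m), 22530 samples/sensor

res <- analyze_session(sim$set)
summary(res)
#> Gait analysis of subject sim
#>   22530 samples/sensor, 4 activity segments
#>   cycles: 297 left, 297 right; pairs: 297 accepted, 0 rejected
#>   walk: 357.0 m, 594 steps, 0.601 m/step, 3.57 km/h, 11 turns
#>   per-minute snapshots (mean deg):
#>     minute 1: sagittal left 4.4 / right -1.9 / pelvis 21.5
#>     minute 3: sagittal left 4.5 / right -2.1 / pelvis 21.5
#>     minute 6: sagittal left 4.4 / right -1.9 / pelvis 21.5
```

The analysis recovers the simulated session: 594 of 595 ground-truth steps
(the terminal contact has no partner), the distance to 3 mm, every one of
the 11 turns, and the configured pelvic tilt in each minute snapshot.
`plot(res)` draws the normalized sagittal shank profiles.

Reliability of repeated measurements — here on a simulated cohort with a
known between-minute correlation:

```r
fit <- reliability(simulate_repeated_measures(200, 3, icc = 0.85,
                                              mean = 7.5, sd = 3.4))
fit
#> Reliability of 3 repeated measurements on 200 subjects
#>   mean (SD): 7.567 (3.273)
#>   Cronbach's alpha: 0.930 (excellent)
#>   ICC(1,1):        0.815 (good)
```

The package bundles the reliability coefficients reported in the
instrument's clinical validation study; banding them reproduces the
published qualitative summary:

```r
table(band_icc(reference_reliability()$icc))
#> excellent      good  moderate
#>         5         1         3
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/imugait.R`:

```sh
Rscript inst/cli/imugait.R simulate    --out session/ --seed 1
Rscript inst/cli/imugait.R analyze     --session session/
Rscript inst/cli/imugait.R reliability --cohort-dir cohort/
```

`analyze` writes `metrics.json`, `cycles.csv`, `profiles.csv`,
`snapshots.csv` and a provenance `run_log.json` (config hash, seed, version,
per-stage counts); every rejected cycle pair is logged with its reason.

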