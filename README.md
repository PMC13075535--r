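# ergolever

Ergonomic assessment of a lever-propelled stair-climbing wheelchair from
surface electromyography (sEMG).

A manual stair-climbing wheelchair is driven by a pull-push lever; how much
muscular effort each stroke demands depends on the seating configuration:
torso angle λ (degrees from the vertical coronal plane), lever distance L
(mm of seat-to-backrest offset) and lever orientation ψ (degrees of forearm
rotation, pronation −/supination +). `ergolever` is for rehabilitation
engineers and assistive-technology researchers who need to turn
multi-channel sEMG recorded during lever propulsion into a seating
recommendation, and to size the chair against anthropometric reach and
clearance standards.

The package implements:

* the sEMG conditioning chain — Butterworth band-pass (default 20–200 Hz,
  order 4, zero phase at 500 Hz sampling), rectified 50-sample
  moving-average envelope, and Hilbert-envelope activation detection with a
  25-sample minimum-duration rule;
* the per-muscle, per-run effort statistic
  `MVC = w₁·A + w₂·RMS` with `A = max(X) − min(X)`,
  `RMS = √(mean(X²))`, `w₁ = 0.7`, `w₂ = 0.3` (a per-task weighted
  statistic — *not* a normalized %MVC), plus the Pearson
  muscle-coordination matrix;
* a Taguchi L9 fractional factorial analysis of the three factors at three
  levels — main effects, 3×3 interaction grids, quadratic response fits
  (`y ~ 1 + x + x²`, R² in percent, residual standard error √(SSE/6)),
  per-muscle optima and the muscle-averaged overall recommendation;
* anthropometric percentile summaries, digital-human-model reach
  constraints (e.g. forward high: `H₁ + E·cos λ + K·sin 45° ≥ 1200 mm`),
  the 360° turning distance `2π(L₁/2 + L₂/2)` and clearance checks against
  IS-7454 / CPWD / CCD / ISO bounds;
* flat-surface usability summaries (task times as mean/SD/SE, Likert score
  mapping, VAS attribute summaries);
* a seeded synthetic-recording generator emulating pull-push cycles
  (BBL/BRD/PDT burst on pull, TBL on push) with known ground truth, so the
  whole chain is testable without hardware.

The study's summary tables ship as plain-text fixtures (`study_table()`),
so the design-of-experiments stages can be run and cross-checked
independently of raw signal processing.

## Worked example

```r
library(ergolever)

report <- run_full_analysis()   # bundled run-by-muscle MVC table

subset(report$main_effects, factor == "torso_angle_deg" & muscle == "BRD")
#>             factor level muscle mean_mvc
#> 3  torso_angle_deg     0    BRD   72.160
#> 7  torso_angle_deg    30    BRD   95.200
#> 11 torso_angle_deg    45    BRD  113.414

report$optima
#>   muscle torso_angle_deg lever_distance_mm lever_orientation_deg
#> 1    BBL               0                50                    30
#> 2    TBL               0                50                     0
#> 3    BRD               0                 0                    30
#> 4    PDT               0                50                     0

report$overall
#>                  factor optimal_setting
#> 1       torso_angle_deg             0.0
#> 2     lever_distance_mm            37.5
#> 3 lever_orientation_deg            15.0
```

Brachioradialis effort rises steeply with torso inclination (72.2 → 113.4
MVC units from upright to 45°), and every muscle prefers the straight
torso; averaging the four muscles' optima yields the overall
recommendation — upright torso, 37.5 mm lever distance, 15° (slightly
supinated) lever orientation.

The same analysis runs on synthetic recordings end to end:

```r
suite <- generate_run_suite(build_l9(),
                            effect_model = list(torso_angle_deg = c(`45` = 1.5)),
                            base_model = signal_model(seed = 7),
                            schedule = burst_schedule(cycle_count = 3))
rep2 <- run_full_analysis(list(source = "suite", suite = suite))
```

Flat-surface usability from the bundled course table:

```r
tt <- task_time_summary(study_table("task_times"))
tt[tt$task %in% c("R", "T1"), c("task", "n", "mean_reported", "se_reported")]
#>   task n mean_reported se_reported
#> 2    R 9          14.8         0.6
#> 3   T1 9          21.6         0.7
```

The ramp (R) and the 90° turn (T1) are the slowest tasks — 14.8 s and
21.6 s on average — which is what the chair's 65 kg mass and ~4.87 m
turning circumference (`turning_distance(wheelchair_geometry())`) would
lead one to expect.

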