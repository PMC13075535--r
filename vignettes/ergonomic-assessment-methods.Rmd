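---
title: "Methods: sEMG-based ergonomic assessment of a lever-propelled stair-climbing wheelchair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG-based ergonomic assessment of a lever-propelled stair-climbing wheelchair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergolever)
```

## The problem

A manually propelled stair-climbing wheelchair is driven by a pull-push
lever: the pull stroke (elbow flexion plus shoulder extension) rotates the
stair-climbing wheel, the push stroke returns the lever. Seating ergonomics
— torso angle $\lambda$ (degrees from the vertical coronal plane), lever
distance $L$ (mm of seat-to-backrest offset) and lever orientation $\psi$
(degrees of forearm rotation, pronation negative, supination positive) —
determine how much muscular effort the stroke demands. The package
quantifies that effort from four-channel surface EMG (biceps brachii long
head BBL, triceps brachii long head TBL, brachioradialis BRD, posterior
deltoid PDT, sampled at 500 Hz) and identifies the seating configuration
that minimizes it, alongside anthropometric reach/clearance checks and
flat-surface usability summaries.

## Signal chain

Raw sEMG is conditioned per channel:

1. **Band-pass filtering.** A Butterworth IIR band-pass. The acquisition
   protocol specifies the filter family but not its corner frequencies or
   order, which are unrecoverable; the package defaults to 20–200 Hz,
   order 4, applied forward–backward (zero phase) — standard sEMG practice
   that keeps the passband inside the 250 Hz Nyquist limit and leaves
   burst peak locations untouched. All three settings are exposed in
   `filter_spec()`.
2. **Envelope extraction.** Rectification (absolute value) followed by a
   centred 50-sample moving average (100 ms at 500 Hz). Edges use a
   truncated (shrinking) window rather than zero padding, so the envelope
   is not artificially depressed at recording boundaries.
3. **Activation detection.** The analytic-signal magnitude (Hilbert
   envelope) of the filtered channel is thresholded adaptively;
   supra-threshold runs separated by gaps shorter than 25 samples are
   merged, and runs shorter than 25 samples are discarded. The 25-sample
   minimum-duration rule suppresses noise and involuntary artifacts.
   Whether detection should run on the filtered signal or on the
   rectified envelope is configurable (`on =` in `detect_activations()`);
   the default is the filtered signal, whose analytic envelope is the
   sharper onset marker.

### The adaptive threshold

No threshold rule is specified by the protocol, so the package had to
choose one. The baseline is estimated from the quietest envelope segments:
the envelope is cut into 50-sample windows and the windows whose mean lies
in the lowest decile of window means are pooled. The threshold is then
`baseline mean + k * baseline SD` with `k = 5` by default.

The multiplier deserves a note. The envelope of band-limited Gaussian
noise is approximately Rayleigh distributed, for which "mean + 3 SD" is
only about the 99.4th percentile — on a few-thousand-sample recording,
chance excursions above such a threshold occur every few hundred samples,
and the gap-merge rule then welds them into spurious events long enough to
survive the 25-sample duration test. Empirically, `k = 3` produced several
false events per noise-only recording, while `k = 5` produced none across
thirty 10-second noise recordings and still sits far below genuine bursts
at 10× the baseline SD. The default is therefore 5, with `threshold_k`
exposed for sensitivity analysis.

Sample indexing is 1-based with inclusive `[onset, offset]` intervals —
the R convention — and all interval bookkeeping (ground truth, duration
rule, pairing) uses it consistently.

## The MVC statistic

Per muscle and experimental run, effort is summarized by a weighted
statistic of the processed series $X$:

$$\mathrm{MVC} = w_1 A + w_2\,\mathrm{RMS}, \qquad
  A = \max(X) - \min(X), \qquad
  \mathrm{RMS} = \sqrt{\tfrac1n \sum_i x_i^2},$$

with $w_1 = 0.7$ and $w_2 = 0.3$: the range term is sensitive to full
recruitment peaks, the RMS term damps outliers. Two caveats are stated
explicitly in the documentation: the name "MVC" follows the field usage in
this line of work but the quantity is a per-task statistic, *not* a
normalized percentage of a calibration maximal contraction (none is
recorded); and the statistic is computed on the full filtered series by
default (matching its definition over the recording), with
`windows_only = TRUE` available to restrict it to detected activation
windows for sensitivity analysis. Muscle coordination is the Pearson
correlation of per-run MVC values between muscle pairs; constant columns
are flagged as undefined rather than silently zeroed.

## Taguchi L9 analysis

The three factors at three levels each would need 27 runs in full
factorial; the study uses the standard L9 orthogonal array (a 1/3
fraction), with level codings exactly as printed in the study design:
$\lambda \in \{0, 30, 45\}$ degrees, $L \in \{0, 50, 100\}$ mm,
$\psi \in \{-30, 0, 30\}$ degrees. These codings matter: the quadratic-fit
intercepts equal the zero-level means only under them.

* **Main effects** are level means (3 runs each); in a balanced L9 the
  mean of the three level means equals the grand mean of all 9 runs,
  which the tests enforce to 1e-9 relative.
* **Interaction grids** average the response over the cross of two
  factors' levels. In an L9 every level pair occurs exactly once, so each
  cell is a single run and two-factor effects are confounded with the
  third factor's main effect; the grids are computed exactly as the study
  computes them, and the confounding caveat is documented rather than
  "corrected".
* **Quadratic fits** regress the 9 run responses on $(1, x, x^2)$ by OLS.
  With three distinct levels at equal replication the curve interpolates
  the level means; $R^2$ is reported in percent and the residual standard
  error as $\sqrt{SSE/6}$. The reported regression table's residual
  column is numerically this residual standard error, not a residual sum
  of squares as its header suggests; the package emits both `residual_ss`
  and `residual_standard_error` with unambiguous names. One reported
  quadratic coefficient (PDT–lever orientation) matches the recomputed
  value in magnitude but not sign; the tests compare that cell in
  magnitude and this is treated as a sign typo in the source table.
* **Optima** pick, per muscle and factor, the level with the smallest
  main-effect mean; ties break toward the lower level index with a
  warning (the study data contain no ties). The **overall
  recommendation** is the per-factor arithmetic mean of the four muscles'
  optimal numeric settings — numeric averaging only, no MVC-weighted
  scheme, matching the reported 0.0°, 37.5 mm, 15.0°.
* **Design-space surfaces** are either bilinear interpolations of the
  observed 3×3 grids (exact at design points) or additive quadratics
  $q_1(x_1) + q_2(x_2) - \bar y$; both report argmin/argmax cells. No
  ANOVA F-tests or Taguchi signal-to-noise analysis are computed — the
  study reports neither.

```{r doe}
report <- run_full_analysis()
report$overall
```

## Synthetic recordings

Because no raw recordings are deposited, the package ships a seeded
generator whose defaults define the study conditions it emulates:
500 Hz sampling, four channels with BBL/BRD/PDT bursting during the pull
phase and TBL during the push phase, bursts of band-limited (20–200 Hz)
Gaussian noise with 25 ms linear edge tapers (which keep detected onsets
stable), superposed on baseline Gaussian noise. The protocol does not
state lever cadence or trial duration, so the package fixes a desk-scale
default of 1.0 s pull / 1.0 s push / 0.5 s rest; amplitudes are in
arbitrary units, as the study's feature tables are unitless and no µV
calibration is attempted. `generate_run_suite()` scales per-run burst
amplitudes by per-level multipliers, so injected factor effects are
recoverable by the DOE stage — the parameter-recovery test injects a 1.5×
multiplier on the inclined torso levels and requires the straight-torso
optimum to be recovered for every muscle in at least 19 of 20 seeded
replicates.

What the generator does *not* model: motor-unit action-potential shapes,
electrode–skin impedance, movement artifacts, mains hum, or
participant-to-participant variability. Passing tests therefore
demonstrate that the analysis chain is correct and self-consistent under
its stated signal model, not that it is robust to every artifact of real
hardware.

Test and example problem sizes (2–3 cycles per recording, 20 replicates
for recovery) were chosen to keep the full suite desk-scale — seconds to
a few tens of seconds on one CPU — while leaving comfortable margins on
every statistical assertion.

## Anthropometry, reach and turning geometry

All geometry is internal in mm (summary tables in cm are converted on
load by the caller; the reach equations are stated in mm). The four
digital-human-model reach constraints use shoulder height above seat $E$
and shoulder-grip length $K$:

| constraint | left-hand side | bound |
|---|---|---|
| forward high | $H_1 + E\cos\lambda + K\sin 45°$ | ≥ 1200 mm |
| forward low | $H_1 + E\cos\lambda - K\sin 45°$ | ≥ 400 mm |
| lateral high | $H_1 + E + K\sin 45°$ | ≥ 1300 mm |
| lateral low | $H_1 + E\sin\tau - K\sin 45°$ | ≥ 250 mm |

$\tau$ (torso angle with the sagittal plane) appears only in the lateral-low
constraint and is never given a value by the protocol, so it is an
explicit geometry parameter. The 360° turning distance is
$2\pi(L_1/2 + L_2/2)$ — the mean-half-lengths reading of the turning
radius, the only reading that reproduces the reported prototype value of
4870 mm (at 600 × 950 mm); the root-sum-of-squares alternative
($2\pi\sqrt{L_1^2+L_2^2} \approx 7060$ mm) is implemented and documented
as inconsistent with that value. Note the exact value 4869.47 mm rounds
to 4870 only at tens precision. A reported ~1450 mm distance for a 90°
turn is not derivable from either reading and is not a package output.

Percentiles are empirical, linear-interpolation-between-closest-ranks
(R's quantile type 7), pinned for cross-implementation reproducibility.
The printed 5th–95th bounds of the bundled anthropometric table are not
everywhere consistent with normal theory at the printed means/SDs (age,
shoulder height); they are treated as fixture data, not validation
targets — the generator draws from the means/SDs.

## Usability summaries

Task completion times use the sample SD ($n-1$; the source does not state
a convention, so the sample convention is pinned) and SE $= SD/\sqrt n$,
with reported values rounded half-up to one decimal second. The prose
summary accompanying the source's task-time table disagrees with the
table itself for several tasks (e.g. straight corridor 4.1 vs 4.0 s, tight
turn 22.3 vs 21.6 s); the package computes from the table only, and only
table-consistent values are asserted in tests. Likert descriptors map
bijectively onto scores 1–4; VAS ratings (0–10) are summarized by mean
and sample SD with lowest/highest flags. Raw per-participant VAS scores
are not published: the bundled attribute means/SDs parameterize a
truncated-normal generator for round-trip testing, and are never claimed
as recomputable outputs.

## Known limitations

* The exact filter corners/order and detection threshold of the original
  acquisition are unknown; reproducing its raw waveform figures is not
  attempted, and signal-level defaults are package choices (all
  config-exposed).
* An L9 cannot separate two-factor interactions from main effects; the
  interaction grids inherit that confounding.
* The MVC statistic is amplitude-scale dependent (arbitrary units);
  cross-study comparisons require a common calibration the data do not
  provide.
* The synthetic generator validates the pipeline, not hardware realism
  (see above).
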