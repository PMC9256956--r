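---
title: "Estimating core temperature from heart rate: models, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating core temperature from heart rate: models, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coretemp)
```

## The estimation problem

During exercise in the heat, core temperature (Tc) rises with accumulated
thermal strain while heart rate (HR) rises with both workload and
temperature. The cardiovascular coupling between the two is strong enough
that sequential HR observations carry usable information about Tc. This
package estimates Tc minute-by-minute from minute-averaged HR with a
scalar extended Kalman filter (EKF), and provides the full validation
machinery needed to judge when that estimate can be trusted.

### State and observation model

The hidden state is core temperature, modelled as a random walk:
$$x_t = x_{t-1} + w_t, \qquad w_t \sim N(0, \gamma^2)$$
This is deliberately not a biophysical heat-balance model: the filter
assumes only that Tc changes slowly between minutes, and lets the HR
observations do the work. The observation model is a four-parameter
sigmoid,
$$\mathrm{HR}_t = m(x_t) + e_t, \qquad
  m(x) = d + \frac{a}{1 + e^{-(x - c)/b}}, \qquad e_t \sim N(0, \sigma^2),$$
chosen because the HR–Tc relation saturates at both ends: HR has a resting
floor ($d$) and a maximal ceiling ($d + a$), with the steepest coupling
(slope $a/4b$) near the midpoint $c$. Each minute the filter inflates its
variance by $\gamma^2$, linearises $m$ at the prior mean and applies the
standard scalar Kalman update (`kalman_step()`).

The key structural assumption is a *fixed* HR–Tc relationship. Anything
that moves HR independently of Tc — dehydration-driven cardiovascular
drift, anxiety, caffeine — is folded into $\sigma^2$ and will bias the
estimate. This is also why the estimator degrades at the hot end of the
range: the sigmoid flattens ($m'$ shrinks), each beat of HR carries less
temperature information, and the filter leans increasingly on its random-walk
prior. The package treats this as a property to be measured (via the
threshold sweep) rather than corrected.

### Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `start_tc` | °C | 37.0 | field deployment: baseline Tc unknown, normothermia assumed |
| `start_variance` | °C² | 0.02 | moderate confidence in the 37.0 start (SD ≈ 0.14 °C) |
| `process_noise_var` ($\gamma^2$) | °C²/min | 0.000484 | allows ≈ 0.022 °C/min drift, the pace of exercise-induced Tc change |
| `obs_noise_var` ($\sigma^2$) | bpm² | fitted | residual mean square of the sigmoid fit |

The sigmoid coefficients themselves have **no hidden defaults**: published
coefficient sets for this estimator live in the prior literature and are
not transcribed here. Users either supply their own coefficients to
`hr_sigmoid()` or fit them from paired data with `fit_sigmoid()`. All of
this package's own validation uses synthetic models that are either known
by construction or fitted to data generated from a known truth, so every
accuracy claim is checked against a ground truth rather than an assumed
coefficient set.

`fit_sigmoid()` uses Levenberg–Marquardt nonlinear least squares with
self-starting values (asymptotes anchored just outside the observed HR
range, midpoint where HR crosses its midrange). It requires at least 8
pairs spanning more than 1 °C: a narrower span cannot separate midpoint
from scale, and the fit refuses rather than returning an unidentified
curve. A perfectly noiseless fit would return a zero residual variance,
which would make the filter trust HR infinitely; the variance is floored
at machine epsilon instead.

## The synthetic cohort

Real paired HR/capsule datasets are scarce, so the package carries a
seeded generator (`generate_cohort()`) that emulates the study design
under which this estimator is typically validated: an incremental cycling
test in the heat — 20 min of warm-up at ~70% of maximal HR, then 3-min
stages of +5% workload to exhaustion. Per-athlete endpoints are drawn from
cohort distributions (baseline HR 82 ± 14 bpm, peak HR 182 ± 12 bpm,
duration 44 ± 10 min, baseline Tc 37.1 ± 0.4 °C, peak Tc 38.9 ± 0.6 °C),
with peaks constrained above baselines by rejection sampling — redrawing,
rather than clipping, keeps the marginal distributions near-normal.

True HR follows the protocol (ramp to plateau, then stage-wise steps
smoothed by a 30-s lag); true Tc follows a first-order lag
$d\mathrm{Tc}/dt = (\mathrm{Tc}_{eq}(t) - \mathrm{Tc})/\tau$ with
$\tau = 10$ min towards a workload-driven equilibrium, scaled so the drawn
peak is reached exactly at the drawn duration. Ten minutes is in the range
reported for intestinal temperature dynamics during steady exercise
transitions; since only endpoint statistics are specified, any smooth
monotone profile consistent with them would serve, and $\tau$ is exposed
in `cohort_spec()` for sensitivity work.

Recorded streams add independent Gaussian sensor noise (defaults: 2 bpm
for a chest strap at 1-s cadence, 0.05 °C for a telemetric capsule at
10-s cadence) and inject, per trace, an exact number of data defects:
contiguous Tc gaps 1–8 min long (so both interpolation branches occur)
and single-sample spikes (+2 to +5 °C on Tc, ±60 bpm on HR) that the
cleaning rules must catch.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: cardiovascular drift decoupling HR from Tc,
inter-individual differences in the HR–Tc curve itself (one curve
generates the whole cohort in model-consistent runs), capsule transit
artefacts, pacing behaviour, or environmental variation within a test.
Model-consistent runs (`hr_from_model = TRUE`) measure the filter under
its own assumptions — a consistency check, deliberately not a field
validity claim.

## Preprocessing rules

The cleaning pipeline replaces manual record review with deterministic,
logged rules:

- **Outlier removal** (`remove_tc_outliers()`): delete Tc samples outside
  35.0–42.0 °C, or interior samples differing from *both* neighbours by
  more than 0.5 °C per 10-s sample. The pass repeats until a fixed point,
  making the operation idempotent; endpoint samples have one neighbour and
  are only subject to the range rule (an end-of-trace spike inside the
  physiological range is accepted — the price of a rule that never deletes
  genuine steep trends at the boundary).
- **Minute averaging** (`minute_average()`): half-open windows
  `[60m, 60(m+1))`, origin at the first sample common to both streams
  (the alignment is a convention; estimates are invariant to it). A
  trailing partial minute is kept when at least half-covered, so test-end
  peaks — exactly where validation matters most — are not discarded.
- **Gap interpolation** (`interpolate_gaps()`): internal missing runs
  strictly shorter than 5 min are filled linearly and flagged; runs of
  5 min or longer set the series' exclusion flag unless an explicit
  override accepts the fill. The pipeline's default is to override with a
  flag — an automated stand-in for the manual curve review this replaces —
  so that no athlete is ever silently dropped; the conservative flag-only
  behaviour remains the function default. HR gaps get the same rule for
  symmetry; they are logged separately.

## Agreement statistics

All statistics work on a paired panel of (Tc, Tc-est) minutes with
`diff = tc_est - tc`.

- **Bias** is tested with a pooled one-sample t-test, the convention in
  method-comparison studies even though pooling ignores within-athlete
  clustering; the repeated-measures machinery below handles the spread.
- **Limits of agreement** use the one-way variance-components correction
  for multiple non-constant measurements per subject: between-athlete
  variance $(\mathrm{MSB} - \mathrm{MSW})/n_0$ with
  $n_0 = (N - \sum n_i^2/N)/(k-1)$, truncated at zero, added to the
  within-athlete mean square before taking $1.96\,\mathrm{SD}$. With one
  record per athlete this reduces exactly to classic Bland–Altman. Both
  the pooled SD and the repeated-measures total SD are reported, labelled,
  since the two answer different questions.
- **Weighted RMSE**: per-athlete RMSE aggregated with weights equal to
  each athlete's retained minutes, i.e. weighting by participant *and*
  test duration; the weighted SD uses the same weights with a
  $\sum n_i$ denominator (a descriptive, not inferential, spread).
- **Peak analysis** (`peak_panel()`) takes the maxima of the observed and
  estimated series *independently* — the estimated peak need not occur in
  the observed peak's minute. This mirrors how peaks are read off
  monitoring dashboards; pairing at the observed peak's minute would
  systematically penalise phase lag, a different question.
- **Subgroup ANOVA** on per-athlete RMSE across sex and discipline; groups
  with fewer than two members are excluded with a notice, and an all-equal
  input returns F = 0 by convention rather than 0/0.

## Threshold diagnostics

`threshold_sweep()` classifies each record at thresholds 37.00–39.75 °C
(0.25 °C steps; 39.00–39.75 °C for peak data): actually positive iff
`tc > threshold`, predicted positive iff `tc_est > threshold`, strict
inequality on both sides — a reading consistent with exceedance labels of
the form "> 38.75". Metrics are exact rationals until the final rounding,
which is **half-up** to integer percent (12.5 → 13); base R's banker's
rounding would disagree with published tables at exact halves. A metric
with a zero denominator is reported as not-applicable, never as 0 or 100,
to avoid silently grading an undefined quantity. Grades band the rounded
percent: ≥90 excellent, 80–89 good, 70–79 fair, 60–69 poor, <60 failure.

The packaged fixture of published confusion counts (101 athletes, 5,025
minutes) is consumed by `check_published_counts()`, which re-derives all
36 metric cells from the 48 raw counts with a ±1 percentage-point
tolerance — absorbing the unknowable rounding convention of the source —
and checks every column against the printed observation total.

## Numerical and design notes

- The EKF linearises at the prior mean only (no iterated update); with a
  large innovation and steep local slope the first update can overshoot
  the target plateau before settling. This is the standard EKF trade-off
  and is covered by the fixed-point tests.
- HR values outside the sigmoid's open range are still assimilated — the
  innovation remains well defined — with a warning, not clamped; clamping
  would hide sensor faults the preprocessing should have caught.
- Missing HR minutes propagate the time update only: the estimate is
  carried forward and its variance grows by $\gamma^2$ per minute.
- Estimates depend only on the order of HR values, never on the minute
  labels (checked by a re-timing invariance test).
- All generators take explicit seeds and restore the caller's RNG state;
  a pipeline run writes a manifest (seed, config checksum, per-file MD5)
  so reproducibility is verifiable, not assumed.

### Problem sizes in the test suite

The suite checks cohort moments at n = 1000 athletes (3 standard errors),
sigmoid recovery at 100 replicates × 500 pairs, fixed-point convergence
over 400 minutes, and a full 101-athlete model-consistent pipeline run —
sizes chosen to make the statistical assertions sharp while keeping the
whole suite fast enough to run habitually.

## Known limitations

- The filter inherits the fixed-relationship assumption; no per-athlete
  calibration is implemented, though `fit_sigmoid()` on an individual's
  historical pairs is the natural route to one.
- The generator is statistical, not mechanistic: no metabolic heat
  production, sweating or clothing model, and no absolute workload in
  watts (no downstream statistic needs it).
- Sensitivity at high thresholds is intrinsically poor when most
  observations sit mid-range; the sweep quantifies this, it cannot fix it.
- The quadratic observation model that preceded the sigmoid version is
  not implemented, and no multi-sensor fusion or real-time streaming is
  attempted.
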