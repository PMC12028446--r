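---
title: "Methods: anomaly-based balance assessment from force-platform stabilometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anomaly-based balance assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balanceAD)
```

## The problem

Standing balance is usually summarized by single-domain posturographic
measures — center-of-pressure (CoP) excursion area, sway velocity, spectral
content — each of which captures one facet of a multi-system process.
`balanceAD` implements an integrated alternative: it learns the joint
distribution of socio-anthropometric characteristics and postural
performance across a cohort, and scores each participant by how *consistent*
their own profile is with that population pattern. Participants whose
profiles do not conform are flagged — an anomaly-detection view of balance
assessment rather than a normative cut-off view.

The pipeline runs from raw force-platform recordings to a per-participant
score and subgroup statistics:

1. **Signal conditioning and CoP computation** (`compute_cop`). The six
   calibrated channels (Fx, Fy, Fz, Mx, My, Mz; forces the participant
   applies to the platform) are low-pass filtered with a zero-lag
   4th-order Butterworth (10 Hz cutoff by default), realized as a
   2nd-order design applied forward and backward — the standard
   biomechanics reading of "fourth-order zero-lag". Edge transients are
   controlled by 1 s odd-reflection padding. The CoP then follows the
   standard applied-load formulas
   `cop_x = -(My + z·Fx)/Fz`, `cop_y = (Mx - z·Fy)/Fz` (sensor-plane
   offset `z` defaults to 0), reported in cm with positive `cop_x`
   anterior and positive `cop_y` to the right.
2. **Sway metrics per condition** (`ellipse_area`, `mean_velocity`,
   `median_frequency`, averaged over a condition's trials by
   `condition_features`). Trials are 60 s at 100 Hz, under the four
   Romberg-style conditions: firm/foam surface crossed with eyes
   open/closed, three trials each; no trimming of trial edges by default.
3. **Feature matrix** (`assemble_features`): 19 variables per participant —
   age, gender (F = 0, M = 1), body mass, height, BMI, foot length, years
   of study, plus area/velocity/median-frequency for each of the four
   conditions, in a fixed documented column order.
4. **Permuted-target network** (`train_bayes_reg` via
   `run_anomaly_pipeline`): a dense 19-20-20-19 network (tanh, logistic,
   linear output) trained so that the *output layer carries the same 19
   variables but with the participant order randomized*. Training uses
   Bayesian-regularization Levenberg–Marquardt (below).
5. **Anomaly score** (`participant_score`): each participant is simulated
   through the trained network and their predicted 19-vector is compared
   with their measured one by a single linear regression; the reported
   R² equals the squared Pearson correlation of the two vectors. Scores
   are min-max normalized to [0, 1] and split at the 25th/75th
   percentiles into three subgroups.
6. **Group statistics** (`group_comparisons`, `multiplication_factor`):
   one-way ANOVA per variable with Bonferroni-adjusted pairwise Welch
   t-tests, Shapiro–Wilk and Levene assumption checks (reported, never
   used to switch tests), and the multiplication-factor (MF) summary
   `MF = value / grand mean`, whose population mean is exactly 1 per
   variable and which reconstructs raw units as `MF × grand mean`.

## The trainer

The network minimizes the regularized objective
`F = β·E_D + α·E_W`, with `E_D` the sum of squared errors over training
rows and `E_W` the sum of squared weights. Inner steps are damped
Gauss–Newton:

```
Δw = −(2β·JᵀJ + (2α + μ)·I)⁻¹ (2β·Jᵀe + 2α·w)
```

with μ multiplied by 10 on a rejected step and divided by 10 on an
accepted one (μ₀ = 0.005, stop at μ > 1e10, gradient tolerance 1e-7,
default cap 10,000 epochs). After each accepted step the evidence
framework re-estimates the hyperparameters with the Gauss–Newton Hessian
`H ≈ 2β·JᵀJ + 2α·I`:

```
γ = N_w − 2α·tr(H⁻¹);   α ← γ / (2·E_W);   β ← (N − γ) / (2·E_D)
```

starting from α = 0, β = 1, where `N_w` = 1219 parameters and `N` is the
number of training error terms. γ is the effective number of
well-determined parameters and always lies in `[0, N_w]`. The model
checkpoint is the epoch with minimum training MSE, which is what the
returned weights reproduce. Initialization is uniform in ±1/√(fan-in),
fully seeded; rows are split 0.85/0.15 into train/test by default; the
split, the initialization and the target permutation all derive from one
master seed through fixed stage counters (`derive_seed`), so a single
integer reproduces the entire analysis byte for byte.

Two numerical notes. First, the output layer is linear (the two hidden
activations are tanh and logistic): targets are scaled to [−1, 1], so a
linear read-out is safe and exactly invertible. Second, the Jacobian of a
multi-output network is block-sparse in the output-layer weights; the
trainer accumulates `JᵀJ` and `Jᵀe` from a dense shared block plus small
per-output blocks in compiled code, which is algebraically identical to
`crossprod` of the full Jacobian (the pure-R reference implementation is
kept and the two are cross-checked in the test suite).

### What the evidence framework does with permuted targets

Because the target for row *i* is the profile of a *randomly chosen other
participant*, there is no generalizable row-wise mapping to learn; the
only population-level optimum is the conditional mean profile. The
evidence updates find exactly that fixed point: γ settles near 15–20 of
1219 parameters, and the network's prediction becomes nearly
input-independent — a regularized estimate of the cohort's typical scaled
profile. The per-participant score `cor(prediction, own profile)²` is
then a *population-consistency* measure: it asks how well a participant's
19-variable profile shape matches what the cohort as a whole looks like.
This is the designed behavior of the score, and it is why the score
regression runs in the model's scaled space: raw units would let
large-magnitude variables (height, mass, age) dominate the 19-point
regression. A raw-space comparison remains available by inverse-scaling
predictions with the stored scaler.

Two affine caveats are inherent to an R²-based score and deliberately not
"fixed": a prediction that is a scaled/shifted version of the real profile
scores perfectly, and a constant prediction or profile is degenerate
(scored 0 with a flag).

## The synthetic cohort

`cohort_spec()` defines the simulated study conditions; its defaults are
the package's fixed reference scenario and are not tuned per experiment:

* **Demographics**: ages uniform on 18–85; ~72% women; height and mass
  jointly normal within gender (F: 158 ± 6 cm, 59 ± 7 kg; M: 172 ± 6.5 cm,
  69 ± 8 kg; correlation 0.5), truncated to plausibility bounds of
  140–189.8 cm and 44–75.9 kg; BMI derived; foot length 15.2% of height
  plus noise; years of study decline with age (−0.1 y/y around a mean of
  16 at age 18, SD 2.5, clamped to 2–22).
* **Sway**: each CoP axis is a stationary AR(1) at 100 Hz with coefficient
  0.995 (slow drift-like sway) whose SD is
  `0.3 cm × (1 + 0.10·(age−18)/10) × 1.5^[eyes closed] × 2.0^[foam]` —
  about a 10% increase per decade of age, a 1.5× penalty for closing the
  eyes and 2× for foam, multiplicative across factors. Trials are
  converted to raw force-platform channels through the exact inverse of
  the CoP formulas (`cop_to_forces`, constant Fz = m·g), so every
  simulated trial traverses the same filtering and feature path as a
  laboratory recording.
* **Planted anomalies**: a configurable fraction of participants receive a
  sway profile inconsistent with their demographics. The default
  mechanism (`"both"`) draws the sway-generating age from a cohort member
  at least 25 years away *and* inverts the condition multipliers, so the
  planted phenotype sways like a different age group and, pathologically,
  *stabilizes* when vision is removed or the surface softens — the
  signature of a disordered sensory response. Ground-truth flags are kept
  separate from anything the model sees.

One design finding is worth recording. The age-mismatch component *alone*
is structurally invisible to the score: after per-column min-max scaling,
a participant whose sway was generated from a donor age is
indistinguishable from a normal participant of that donor age paired with
someone else's demographics, and since the network's prediction is nearly
input-independent, the score cannot register the joint demo–sway
inconsistency even though the features carry it perfectly (a simple
age-regression residual analysis recovers such plants 10/10). The
condition-response inversion is what creates a *within-profile*
inconsistency that a population-consistency score detects. The default
phenotype therefore includes it; users studying the purely demographic
mismatch can select `anomaly_mechanism = "age_mismatch"` and should pair
it with a score designed for conditional (demographics → sway) modeling.

What the simulator does **not** emulate: inverted-pendulum biomechanics,
inter-trial learning or fatigue, individual sway variability beyond the
age trend, heavy-tailed or non-stationary sway, measurement noise in the
force channels (available as an option in `cop_to_forces` but off by
default). Passing recovery tests on this cohort therefore demonstrates
that the pipeline detects profile-inconsistent participants under its
own stated model, not that it screens clinical populations.

## Numerical and statistical choices

* **Ellipse area**: 95% prediction ellipse under a bivariate-normal sway
  model, `π·χ²₀.₉₅(2)·√(λ₁λ₂)` from the eigenvalues of the 2×2 sample
  covariance; degenerate clouds return 0 (with a warning when all points
  coincide).
* **Median frequency**: Welch PSD (5 s Hann windows, 50% overlap) on each
  mean-removed axis; the half-power frequency is linearly interpolated
  between bins and averaged across the two axes (the averaging choice is
  one of several defensible estimators; it is recorded in the feature
  metadata). The Welch estimator is implemented in the package because no
  installed dependency provides one; it is validated against analytic
  spectra in the tests.
* **Filter response**: the two-pass 2nd-order Butterworth has amplitude
  gain exactly 1/2 at its cutoff (two −3 dB stages) and zero phase; the
  tests assert both.
* **Percentiles**: linear interpolation of order statistics
  (`h = p(n−1)`, `quantile` type 7); group boundaries are inclusive to
  the middle group, so `n = 100` distinct scores split exactly 25/50/25.
* **Scaling**: per-column min-max to [−1, 1] fitted on training rows only;
  test rows may extrapolate outside the interval (retained, logged);
  constant columns are flagged and mapped to 0; targets reuse the input
  scaler since they are the same variables. Gender enters as a single 0/1
  column.
* **Permutation**: drawn uniformly (identity and fixed points permitted —
  "randomized", not a forced derangement), stored in the model for exact
  reproducibility.
* **Degenerate statistics**: constant responses inside a subgroup yield
  `NA` p-values (ANOVA/t-test) or skip flags (Shapiro–Wilk at n < 3)
  rather than errors; assumption-test outcomes are reported but never
  trigger an automatic nonparametric fallback.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline at the
package's reference scale: 150-participant cohorts (12 × 60 s × 100 Hz
trials each), 500-epoch training runs, and a 20-seed recovery experiment
with 10 planted anomalies, alongside smaller cohorts for file-format and
orchestration checks. These sizes were chosen to mirror the reference
scenario while remaining comfortable on a single CPU.

## Known limitations

* The anomaly score is relative to the analyzed cohort (min-max
  normalization and percentile grouping are cohort-internal); scores are
  not transferable across cohorts without re-normalization.
* With permuted targets, train/test R² in scaled space are low by
  construction (there is nothing row-wise to generalize); pooled R² in
  raw units is dominated by between-variable magnitude and should not be
  read as model quality.
* The score's affine invariance and its dependence on the cohort's
  dominant covariance axes mean that subgroups partly reflect age and
  education gradients; this is inherent to the method and mirrors how the
  subgroups are interpreted downstream.
* A 19-point regression has a wide null distribution (E[R²] = 1/18 for
  independent vectors), so single-participant scores carry substantial
  sampling noise; subgroup statistics, not individual scores, are the
  intended readout.
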