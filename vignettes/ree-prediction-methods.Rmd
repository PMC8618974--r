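---
title: "Methods: neural-network prediction of resting energy expenditure in critically ill children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-network prediction of resting energy expenditure in critically ill children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resting energy expenditure (REE, kcal/day) anchors nutritional prescription
in the pediatric intensive care unit. The gold standard is indirect
calorimetry: respiratory gas exchange is measured for about 30 minutes and
converted to a caloric equivalent. Where calorimetry is unavailable,
clinicians fall back on predictive equations (Harris–Benedict, Schofield,
Oxford, FAO/WHO/UNU, the Talbot tables, the VCO~2~-based Mehta equation)
that are known to misestimate REE in critical illness. `picuree` implements
a complete, testable pipeline for the alternative approach: a small
supervised neural network whose inputs and train/test split are chosen by a
genetic algorithm, benchmarked against the classical equations with a common
statistics suite.

Because no patient-level data are publicly deposited for this problem
setting, the package ships a synthetic-cohort generator with known ground
truth; every downstream stage is exercised against that stated world.

## Calorimetry processing

A measurement is a minute-resolution series of VO~2~, VCO~2~ and minute
ventilation. A *steady state* is any contiguous window of at least 5 minutes
in which RQ varies by less than 5% and each of VO~2~, VCO~2~ and minute
ventilation by less than 10%. Three numerical choices are ours, because the
criterion's operational details are conventionally left unstated:

* **Variation statistic**: range/mean over the window. The coefficient of
  variation is available via `method = "cv"`.
* **Window search**: all contiguous windows are scanned; the longest
  qualifying window wins, earliest start on ties.
* **RQ series**: RQ variation is computed on the per-minute RQ values, not
  on ratios of window means.

A valid measurement additionally requires the window RQ to lie in
[0.67, 1.3]; the bounds are inclusive (only RQ strictly below 0.67 or above
1.3 is excluded). REE is the modified Weir value of the window-mean gases,
`1440 * (3.941*VO2 + 1.106*VCO2)` kcal/day, without urinary-nitrogen
correction; the coefficients live in the versioned constants file, not in
code.

## Anthropometry

Growth z-scores use the LMS (Box–Cox) parameterization,
`z = ((x/M)^L - 1)/(L*S)` (or `log(x/M)/S` at `L = 0`), with piecewise-linear
interpolation of L, M, S along the reference grid. The bundled reference
table is **synthetic** — smooth plausible pediatric curves, labelled as such
in its filename — because redistributing the WHO tables is not needed for a
self-contained test world; real tables in the same CSV schema can be dropped
in. Weight-for-age is limited to 10 years and weight-for-length/height to
5 years, reproducing the structured missingness those chart limits cause in
mixed-age cohorts.

Status classes follow the WHO-style cut-offs with strict inequalities:
stunting `z_hfa < -2`; wasting graded at −1/−2/−3 on weight-for-length/height
below 5 years and on BMI-for-age from the 5th birthday (the "≥ 5 years"
branch includes the birthday itself); overweight `z > 2` (under 5) or
`z_bmi > 1` (5 and over); obesity `z > 3` / `z_bmi > 2`, taking precedence
over overweight.

## The equation registry

All ten classical estimators are evaluated from a versioned CSV registry
(coefficients per sex and half-open age band `[lo, hi)`, units fixed as kg,
cm, years, kcal/day), each row carrying its citation. Decisions:

* The interior band edges (ages 3 and 10) belong to the upper band.
* Talbot tables default to nearest-abscissa lookup (ties to the lower row),
  since the originals are discrete; linear interpolation and a strict
  out-of-range policy are selectable. The bundled tables are abridged
  transcriptions of the commonly reproduced values.
* The Mehta equation is `5.534 kcal/L × VCO2 × 1440` and is evaluated only
  for mechanically ventilated records; its coefficient awaits a
  primary-source check and the Harris–Benedict infant variant
  (`22.10 + 31.05·W + 1.16·H`, age < 1 year) is flagged `placeholder` in the
  registry status column for the same reason.
* Missing required inputs make an equation *not applicable* (`NA`), never an
  error; cohort-level evaluation is total.

## Synthetic cohort: the stated world

The generator is calibrated once to the published marginal summaries of a
257-child PICU cohort and then frozen. The generative model is our choice
and is fully exposed in `cohort_spec()`:

* sex ~ Bernoulli(0.564); ethnicity (Caucasian/Asian/South American/African)
  ~ (0.80, 0.08, 0.08, 0.04) — the source reports no ethnic breakdown, so
  the probabilities are a plausible European single-center mix;
* age ~ log-normal (meanlog `log 2.9`, sdlog 1.4, truncated to
  [0.1, 17.5] years), giving a median near 2.4 years with the long right
  tail typical of PICU admissions;
* weight and height by inverting the LMS curves at correlated per-child z
  draws (means −0.9/−1.2, SDs 1.4/1.6, correlation 0.7, truncated at ±3.5),
  emulating the undernourished skew of the reference cohort;
* VO~2~ = `0.01215 · weight^0.75 · (1 + ε)`, ε ~ N(0, 0.18²) — Kleiber-type
  allometry with the coefficient calibrated so the cohort mean is
  0.09 L/min; RQ ~ truncated normal on [0.67, 1.3] with pre-truncation
  location 0.6814 and SD 0.12, calibrated so the *truncated* mean is 0.77;
  VCO~2~ = RQ·VO~2~ exactly;
* vitals and labs are drawn from the published means/SDs (CRP log-normal to
  match its median/IQR reporting); missingness is MCAR at configurable
  per-variable rates, with gas and core anthropometric fields protected.

Two ground-truth mechanisms are available. Under `weir_exact` the true REE
*is* the Weir value of the generated gases, so gas-aware models can in
principle be exact and the no-gas models see signal only through the
weight–VO~2~ allometry. Under `covariate_driven` the truth is
`55·weight + 40·male + 35·(temperature − 36.6) + N(0, 50²)` kcal/day —
arbitrary but documented, with weight dominant.

The per-patient breath series places a steady window (default minutes 8–22)
with ±1% multiplicative gas noise inside and a compounding 6%/min VO~2~-only
drift outside, so the RQ criterion rejects any window touching off-steady
minutes; the construction guarantees the detector recovers the true window.

**What a green test does not establish.** The generator reproduces marginal
moments and one chosen dependence structure; it does not emulate the joint
distribution of vitals/labs with REE (unknown from the source), diagnosis
mix, ventilation physiology, or clinician-driven (non-MCAR) missingness.
Recovery results on this world demonstrate that the pipeline works as
specified, not that its clinical accuracy equals the published figures.

## Input selection and split matching

The published system ("TWIST") couples an evolutionary input selector with a
distribution-matched two-way split, driven by a proprietary genetic
algorithm. We reimplement the *contract* with a standard elitist GA:
tournament selection (size 3), uniform crossover (rate 0.9), per-bit
mutation (default 1/chromosome length), elitism 2, population 50,
generations 100 — defaults declared in `ga_config()`, none claimed from the
source. The chromosome is the concatenation of a feature mask and a record
assignment; halves are repaired to within ±10% of equal size (the published
analysis used a 125/132 split, so equality is not forced). A config switch
(`staged`) optimizes the split first and the mask second, to probe
sensitivity to the joint design.

Fitness is the mean of the two blind reversal scores (negative MAE by
default) minus `distribution_penalty_weight` times the mean distributional
distance between halves — two-sample Kolmogorov–Smirnov statistic for
continuous variables, absolute proportion difference for binary ones —
computed over **all candidate inputs plus the target** (matching on inputs
only is the obvious alternative; we match the target too since the split
should balance the outcome being predicted). An optional per-feature penalty
(default 0) makes parsimony pressure explicit; by default it is implicit in
the blind-test objective. Masked features that are constant within a
training half are dropped fold-locally; a mask with no usable feature scores
`-Inf`.

## The regressor and the reversal protocol

The network is a single-hidden-layer perceptron with four hidden tanh units
and a linear output, trained by full-batch Adam (step 0.02, up to 600
epochs) on z-standardized inputs and target, with early stopping on a 10%
held-out slice of the training half (patience 150) and three random restarts
keeping the best monitor loss — small full-batch networks stall in poor
local optima often enough that restarts materially change blind accuracy.
All of activation, epochs, stopping and scaling are declared in
`mlp_spec()`; the original training regime is unrecoverable, so acceptance
rests on recovery properties, not weight equality.

The reversal protocol trains on half A to predict half B and vice versa;
scalers are fit on the respective training half only, so each record's blind
prediction never depends on its own half's targets (fold isolation is
tested). Metrics are reported both pooled over all records and averaged over
the two testing halves, the latter matching the published reporting
convention.

## Comparison statistics

For each method: MAE; mean relative error (mean of per-record
`|pred − true|/true`); `accuracy_abs = 100·(1 − MAE/mean(true))`;
`accuracy_rel = 100·(1 − MRE)`; squared Pearson correlation; and the
two-sample F statistic oriented as `(sd_true/sd_pred)²` with a two-tailed
p-value on `(n−1, n−1)` degrees of freedom. The accuracy definitions and the
F orientation were inferred by exact agreement with the published summary
table and adopted as definitions; the identities are machine-checked on
every emitted report. Subgroup rows (the VCO~2~ equation on ventilated
children, the infant equation under 1 year) are computed on their applicable
subgroup — the published ventilated-only footnote SDs reconcile only under
that reading. Significance is flagged at p < 0.001 (the source's
multiple-testing allowance) without further adjustment.

## Known limitations

* The equation registry transcribes coefficients from standard secondary
  sources; two entries (`mehta` k, the infant Harris–Benedict form) are
  explicitly awaiting primary-source verification and are marked in the
  registry.
* The GA is a contract-level stand-in for the proprietary original;
  selected-variable lists should be compared qualitatively, not
  name-for-name.
* Published patient-level results are not reproducible from this package by
  construction (the data are not deposited); the acceptance surface is the
  summary-statistic identities plus parameter recovery on the synthetic
  world.
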