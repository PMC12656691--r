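---
title: "Deriving default dermal absorption values: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving default dermal absorption values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermabs)
```

## The problem

Dermal absorption values convert dermal exposure to a plant-protection
product into systemic exposure. When an applicant submits no study, risk
assessment falls back on *default values*: percentages of applied dose,
set per formulation type category (organic solvent, water-based, solid,
other) and concentration status (concentrate vs. dilution), that must be
conservative enough that absorption for most new substances falls below
them. `dermabs` implements the two established derivation routes — an
empirical percentile approach and a Bayesian mixed-model approach — plus
the preprocessing conventions for harmonised in vitro study records, and
a synthetic-data generator with known ground truth against which the
whole chain is validated.

## Preprocessing rules

Records are per-replicate rows of an in vitro (diffusion cell) study:
fractions of the applied dose recovered in the receptor fluid, the
chamber wash, the whole skin, and a sequence of tape strips (strip 1
outermost), together with experiment-level summaries.

* **Recovery filter.** Experiments with mean mass-balance recovery
  strictly below 90% or strictly above 110% are removed whole; exactly
  90 and exactly 110 are retained. The mean is an experiment-level
  quantity (all replicates of a tested concentration within a study
  share it), so the filter acts on experiments, not single replicates.
  Records with missing recovery are excluded with a warning — silently
  keeping unverifiable mass balances would bias the tails the defaults
  are built from.
* **Tape-strip rule.** If at least 75% of the material was absorbed on
  average after half the sampling duration (equality counts), absorption
  is considered essentially complete and *all* strips are excluded;
  otherwise only strips 1–2 (surface material) are excluded and deeper
  strips count as potentially absorbed. A missing half-duration value
  defaults to the conservative incomplete branch (keep strips 3+,
  configurable via `missing_policy`), which can only increase the
  absorption fraction.
* **Potential absorption** is receptor fluid + chamber wash + skin +
  retained strips. Values at or outside (0, 1) are rejected, never
  clamped: observed fractions in this data class span roughly 1e−5 to
  0.8, so a boundary value indicates a recording error, and silent
  epsilon-clipping would manufacture extreme logits.

The logit transform `y = log(f/(1−f))` is applied without any boundary
handling for the same reason.

## The empirical route

Per category×status cell the default-value candidates are the sample
95th percentile and its distribution-free upper 95% confidence limit:
the *k*-th smallest observation, where *k* is the smallest integer with
`pbinom(k, n, 0.95) ≥ 0.95`. The percentile uses linear interpolation
between order statistics (R's default type-7 convention; exposed as
`quantile_type` since other conventions shift the value for small
cells), while the confidence limit is always an exact order statistic —
interpolating it would forfeit its distribution-free coverage guarantee.
Replicate-level values are pooled per cell (cell sample sizes then match
replicate counts). The approach ignores the clustering of replicates
within substances and studies; it is included for comparability, and its
limited generalisability is exactly what motivates the model route.

## The mixed model

For replicate *i* in within-study group *g*, study *j*, substance *s*
with status *c(i)*:

$$y_i = \alpha + \beta_C\,\mathbb{1}[\text{conc}] + \beta_{cat}
 + u_{s,c(i)} + v_j + w_g + e_i$$

with $(u_{s,D}, u_{s,C})^\top \sim N(0, G)$ a status-specific substance
random slope (2×2 covariance, correlation ρ), $v_j \sim N(0,
\sigma^2_{study})$, $w_g \sim N(0, \sigma^2_{within})$ (the group is the
same substance × formulation × target concentration within a study) and
$e_i \sim N(0, \sigma^2_e)$. References are *dilution* and *organic
solvent*. A skin-donor effect is deliberately not modelled: donor
identifiers are rarely reliable in practice, and donor variation within a
study is largely absorbed by the study intercept.

**Sampler.** The conjugate structure of the Gaussian model admits an
exact blocked Gibbs sampler, implemented here without external MCMC
dependencies: per sweep, (1) all location effects (fixed + random) are
drawn jointly from their Gaussian full conditional via a sparse Cholesky
factorisation (`Matrix`), which avoids the slow mixing of single-site
updates when effects are correlated with the intercept; (2) the scalar
variances from scaled inverse-χ² full conditionals; (3) `G` from an
inverse-Wishart full conditional, with an explicit positive-definiteness
check on every draw. Given a seed the chain is fully deterministic.

**Priors** (all overridable in `default_priors()`): N(0, 1e8) per fixed
effect, scaled inverse-χ²(df = 1, scale = 1) on scalar variances, and
inverse-Wishart(df = 3, scale = I₂) on `G` — weakly informative proper
priors in the convention of standard animal-model MCMC packages, chosen
because the analysis this mirrors does not publish its priors. With
~2000 replicates the likelihood dominates all of them.

**Chain defaults**: 2500 sweeps, 500 burn-in, no thinning → 2000
retained draws, matching the effective-sample-size order of magnitude of
the reference analysis. ESS is estimated with the initial-positive-
sequence autocorrelation estimator; intervals are 95% highest-density
intervals (shortest window over sorted draws); point summaries in
coefficient tables are posterior means. ρ is reported as a derived
quantity of the `G` draws.

## Prediction intervals and default values

Per posterior draw and cell, the upper limit of a two-sided 90%
prediction interval for mean absorption of new substances is

$$100 \cdot \mathrm{logit}^{-1}\!\big(lp + z\sqrt{V}\big), \qquad
z = \Phi^{-1}(0.95) \approx 1.6448536$$

kept at full double precision (the rounded 1.645 shifts borderline cells
across integer rounding). `V` is the status-specific substance variance
(σ²_{S:D} for dilutions, σ²_{S:C} for concentrates — the random-slope
structure estimates them separately), optionally plus the study variance,
optionally plus the within-study variance. The residual variance is never
included: the interval targets mean absorption of new
substances/studies/concentrations, not single replicates. Monotonicity
across the three levels holds draw-wise by construction and is asserted
in the tests. Summaries are the posterior median and the more
conservative 95th percentile; report tables round to integer percent
(cell means to one decimal), machine-readable outputs keep full
precision.

**Plug-in reconstruction.** Evaluating these formulas on a single
pseudo-draw equal to published posterior means (`posterior_from_means()`,
`reference_posterior_means()`) reproduces the published cell means (8.8,
0.9, 3.6, 4.7%) exactly and the all-three-variance posterior medians to
the printed integer for five of the eight cells (48, 32, 3, 6, 4%).
Because the inverse logit is nonlinear, the plug-in of posterior means
does not equal the posterior median of the plug-in; for most cells the
discrepancy vanishes under integer rounding, but for solid dilutions the
plug-in gives 27% against a printed 26% — that cell (and the remaining
two) is therefore not used as a reconstruction check. Full-posterior
agreement would require refitting the published dataset, which the
pipeline supports via its CSV interface.

## Concentrate definitions

The primary definition takes the commercially available undiluted
product as the concentrate (a per-record flag). The alternative
regulatory definition classifies by target concentration: strictly above
50 g/L (50 g/kg for solids, treated as numerically interchangeable) is a
concentrate; exactly 50 is a dilution, following the corrigendum wording
that defines dilutions as "equal to or lower than" the cut-off.
`run_pipeline(definition = "both")` fits the model under each definition
and tabulates per-cell differences of the rounded defaults. Unknown
formulation codes are an error rather than binned into "other" — "other"
is a closed set (GD, CS, ZC), and silently accepting new codes would
misclassify them.

## The synthetic-data generator

`generate_logit_dataset()` draws the exact hierarchy the model assumes:
substance effect pairs from `G`, study and group intercepts, i.i.d.
residuals. Its defaults *are* the reference conditions: parameters at
the published posterior means, a residual variance of 0.25 (the source
analysis does not print σ²_e; 0.25 sits below the smallest printed
variance component, consistent with replicate scatter within groups),
155 substances with shifted-Poisson study/group/replicate counts
calibrated to yield ≈356 studies and ≈6300 replicates, and cell weights
proportional to the replicate counts of the source dataset's overview
table. Formulation categories are allocated per *study* by largest
remainder (every category populated, at least one study each): real
substances appear in several formulation types, and this keeps the
sparse "other" category (~3% of replicates) identifiable at reduced
scales. Target concentrations are log-uniform on [0.003, 960] g/L with
status-dependent sub-ranges overlapping the 50 g/L cut-off, so the two
concentrate definitions genuinely disagree on some groups.

`generate_raw_records()` decomposes each generated fraction into
compartments such that preprocessing recovers it exactly (to 1e−12),
with configurable shares of experiments planted outside the recovery
window and on the complete-absorption branch. This gives planted-truth
tests of every rule boundary and an end-to-end
generate → preprocess → fit → predict validation.

What the generator does *not* emulate: concentration-dependent absorption
within a status (the real inverse concentration–absorption relationship
is only captured through the status fixed effect and group variance),
unequal replicate variance, non-Gaussian logit-scale tails, and missing
data patterns. Passing recovery tests therefore demonstrate correctness
of the implementation under the model's own assumptions, not robustness
to their violation.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
brute-force binomial-CDF summation for the order-statistic index (all n
up to 500), the closed-form Bayesian regression posterior for the
sampler with random effects disabled (Kolmogorov–Smirnov distance on
marginals), REML estimates from `lme4` on a common synthetic dataset for
the full model, closed forms for ESS (white noise, AR(1)) and HPDI
(Gaussian, uniform). Parameter recovery runs five replications at a
reduced scale — 40 substances, ~100 studies, ~2000 replicates, 2000
retained draws — chosen so the whole suite completes in a few minutes;
95% HPDIs cover the generating values for at least 8 of the 10 reported
parameters in at least 4 of 5 replications. Posterior-mean accuracy of
the fixed effects at this scale is limited by design sparsity, not
sampler quality: the "other" category carries ~3% of the data, so
β_other is confounded with its few substance/study effects and its
expected posterior-mean error (~0.5 on the logit scale) matches its
posterior spread; the remaining fixed effects recover to ~0.1.

## Known limitations

* Defaults derived here inherit the concentrate/dilution dichotomy; a
  dose–response model of absorption against applied concentration would
  refine them but is out of scope.
* The empirical route's confidence limit assumes i.i.d. sampling, which
  clustered replicate data violate; it is provided for comparability.
* Single-chain sampling by default; multi-seed runs are cheap and the
  deterministic seeding makes them reproducible, but no automatic
  convergence diagnostic beyond ESS is applied.
* The plug-in reconstruction is an approximation to full-posterior
  summaries, exact only up to rounding (see above).
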