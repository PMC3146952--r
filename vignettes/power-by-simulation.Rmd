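---
title: "Estimating design power by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating design power by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powersim)
```

## Why simulate power

Analytic power formulas exist for parallel trials randomized at the
individual or cluster level, but they run out quickly: two treatments
deployed at different levels, correlation at both the village and the child
level, repeated measures, and attrition have no convenient closed form in
combination. Simulation replaces the derivation with computation. The
procedure is:

1. Choose a data-generating model (DGM) — the same mixed-effects model that
   underlies the conventional formulas — and fix its nuisance parameters,
   ideally estimated from an existing *training dataset* of the same
   outcome in a comparable population.
2. Build the trial population and randomize treatment at the level(s) the
   design prescribes.
3. Draw the random effects and errors, producing one complete simulated
   trial dataset.
4. Analyze it exactly as the real trial will be analyzed and store the
   p-value of the test of interest.
5. Repeat thousands of times; the fraction of p-values below α estimates
   the design's power.

`empirical_power()` runs steps 2–5 from a single `scenario()` object;
`estimate_variance_components()` performs step 1.

## The data-generating models

Three DGMs are built in, all with normal random effects that are
independent of each other and of the errors, and all parameterized by
**standard deviations**, never variances.

**Continuous two-level** (`continuous_params()`):
$y_{ij} = \mu + \beta_1 A_i + b_i + \varepsilon_{ij}$, with
$b_i \sim N(0, \sigma_g)$ shared by every child in cluster $i$ and
$\varepsilon_{ij} \sim N(0, \sigma_e)$. The intraclass correlation is
$\rho = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ (`icc()`), and the total
outcome variance $\sigma^2 = \sigma_g^2 + \sigma_e^2$.

**Binary two-level** (`binary_params()`):
$\mathrm{logit}(p_{ij}) = \mu + \beta_1 A_i + b_i$,
$y_{ij} \sim \mathrm{Bernoulli}(p_{ij})$, with $\mu$ the log-odds of the
control-arm prevalence and $\beta_1$ a log odds ratio.

**Factorial three-level** (`factorial_params()`): a cluster-level treatment
$A$ (e.g. village sanitation mobilization) crossed with a unit-level
treatment $X$ (e.g. household nutrient supplementation), measured at
baseline ($t=0$) and follow-up ($t=1$):
$y_{ijt} = \mu + \beta_1 A_{ijt} + \beta_2 X_{ijt} + \beta_3 A_{ijt}X_{ijt}
 + b_i + b_{ij} + \varepsilon_{ijt}$,
with village, child, and occasion-level components. Exposure indicators are
time-indexed and equal 0 on baseline rows, so the single formula covers the
pre-treatment measurement without a separate baseline model. The model as
written has no secular-trend (time main effect) term; the default
*analysis* model nevertheless includes a time indicator, so the analysis is
robust if a trend were added to the DGM.

## Randomization and its conventions

`build_frame()` expands the design into one row per unit per measurement
occasion; `randomize()` assigns treatments. Two conventions matter:

- **Balanced complete randomization.** Cluster-level treatments go to
  exactly half the clusters (a random permutation, not per-cluster coin
  flips), and unit-level treatments to exactly
  `unit_allocation_fraction × units_per_cluster` units in every cluster.
  Exact balance reflects how such trials are actually allocated and removes
  a source of pure Monte-Carlo noise. Within-cluster allocation could
  equally be Bernoulli; exact balance is the pinned interpretation.
- **Assignment is redrawn every replicate** by default, so the power
  estimate averages over assignments as well as outcomes. Setting
  `redraw_randomization = FALSE` draws one assignment up front and redraws
  only random effects and errors, which is the other common convention;
  with hundreds of clusters the two are practically indistinguishable.

Dropout (`apply_dropout()`) removes each child's follow-up row
independently with the declared probability — missing completely at
random, per the design assumption; informative dropout is out of scope.

## The analysis stage

Each replicate is analyzed with a *marginal* regression — OLS for
continuous outcomes, maximum-likelihood logistic for binary — rather than a
mixed model: marginal estimators with cluster-robust standard errors make
fewer distributional assumptions and are far cheaper inside a
10,000-replicate loop. The covariance is the clustered sandwich estimator
(score contributions summed within cluster) with the small-sample factor
$G/(G-1)$, where $G$ counts clusters at the *highest level of correlation*
(villages, even for the household-level treatment in the factorial design).

The Wald statistic is referred to a **t distribution with G − 1 degrees of
freedom** by default. This is the standard convention for cluster-robust
inference and it matters below roughly 50 clusters: with 40 clusters, a
standard-normal reference rejects a true null about 5.4% of the time at
α = 0.05 and overstates power by about 1.5 percentage points relative to
the analytic benchmark, while t(G−1) is calibrated to within Monte-Carlo
error (the package's test suite measures both). A `"normal"` reference
remains available for the large-G limit.

**One-sided tests.** The one-sided p-value is defined as half the
two-sided p-value. Under a true null a one-sided test at level α therefore
rejects with probability 2α — 10% at α = 0.05 — because either direction
can produce a small p-value. This is the convention the calibration
diagnostic expects.

For the factorial design the fitted analysis model is
`y ~ time + A + X + A:X` over both timepoints with SEs clustered on
village, testing each of the three coefficients marginally (no multiplicity
adjustment — the three hypotheses are reported separately). A
follow-up-only analysis can be specified by passing a custom
`analysis_spec()` without the time term to data restricted to follow-up.

Replicates whose fit does not converge (logistic separation, for instance)
are dropped from the denominator and counted; if more than 1% fail the run
errors out rather than report a biased estimate. Separation is detected
both from glm's own warnings and from fitted log-odds coefficients
exceeding 15 in magnitude, beyond which IRLS can report spurious
convergence.

## Variance components from training data

`estimate_variance_components()` fits an intercept-only mixed model with a
random intercept per grouping level: REML for linear outcomes (less biased
SD estimates than ML at modest cluster counts) via `lme4::lmer()`, and
adaptive Gauss–Hermite quadrature (`nAGQ = 7`) for binary outcomes via
`lme4::glmer()`. A level's SD is only identified if the data contain
repeated observations at that level — multiple children per cluster for
$\sigma_g$, multiple measurements per child for the child-level SD — and a
missing level is a named error. Degenerate estimates are returned as 0.

## Synthetic training cohorts

The two built-in `training_profile()`s emulate the *statistical structure*
of field anthropometry cohorts so the full workflow is runnable and
testable without any data download:

- `"east-java"`: 2,090 children in 160 villages, HAZ mean −0.875,
  village/child SDs 0.482/1.297 (total SD 1.384, ICC 0.12), one
  measurement per child.
- `"india-longitudinal"`: 1,236 children in 25 villages, mean −1.98, SDs
  0.297/1.259/1.079 (village/child/occasion; total SD ≈ 1.68), up to two
  measurements per child, the second retained with probability 0.9 (the
  cohorts report "up to two" without a rate; 0.9 is pinned and
  documented).

Cluster sizes are multinomial around the mean rather than equal, emulating
field imbalance; the real cohorts' size distributions are unpublished, so
the multinomial is a declared stand-in. The generators reproduce means and
variance components — not age structure, covariates, spatial pattern, or
non-normal tails. Tests that pass on these fixtures therefore validate the
estimation machinery, not the realism of any particular field dataset.

## Calibration diagnostics

`null_calibration()` guards the whole pipeline: it refuses any scenario
with a non-zero effect, re-runs the engine, and reports (i) the rejection
rate at α, which must match the nominal level (5% two-sided, 10%
one-sided); (ii) a Kolmogorov–Smirnov test of p-value uniformity
calibrated by parametric bootstrap (size-matched Uniform(0,1) resamples,
1,000 by default); and (iii) a QQ table of sorted p-values against
plotting positions $(k - 0.5)/R$ (any standard convention would do; one is
pinned). Binary-outcome runs are annotated rather than failed: logistic
p-values are discrete in small samples and need not be exactly uniform.

## Numerical and reproducibility choices

- A scenario's master seed seeds a draw of one sub-seed per replicate;
  each replicate re-seeds the RNG before drawing. Results are therefore
  bit-identical across runs and independent of how replicates are batched.
- Random draws within a replicate are ordered deterministically: cluster
  effects in cluster-id order, then child effects, then residuals.
- `mde_search()` brackets and bisects the effect size; the analytic
  backend stops when power is within `tolerance` of the target, the
  simulation backend when the target falls inside the estimate's 95%
  Monte-Carlo interval. Power is monotone in the effect, so bisection is
  safe; an unbracketable target is an error, not an extrapolation.
- The analytic benchmark (`analytic_power()`) is the standard two-arm CRT
  normal-approximation formula with design effect $1 + (n-1)\rho$; it is
  validated against the simulation engine in the test suite, with
  agreement within 3 Monte-Carlo SEs across 20–200 clusters per arm.

## Problem sizes used in the test suite

Calibration checks run the 2-arm × 100-cluster × 10-child design at
10,000 replicates; the simulation-vs-analytic comparison uses 1,000
replicates per grid point over 20–200 clusters per arm; the factorial
grid (60/110/160 villages per arm, 20 households each, 10% dropout) uses
1,000 replicates per point; variance-component recovery averages 20
fixture seeds. These sizes put Monte-Carlo error well below the effect
sizes being detected while keeping a full run of the suite within a few
minutes on one core.

## Known limitations

- Random effects are normal and homoscedastic by construction; real HAZ
  data can be skewed or heteroscedastic, and power against such
  alternatives may differ.
- Dropout is MCAR at the child level; informative or item-level
  missingness is not modeled.
- Only two timepoints, one unit-level allocation fraction, and 1:1
  cluster allocation are supported.
- The binary DGM has no child-level random effect (single measurement per
  child), and three-level variance estimation is implemented for linear
  outcomes only.
- Power for non-Wald tests (permutation, rank-based) and non-normal
  outcome families (counts, survival) is out of scope.
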