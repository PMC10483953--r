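---
title: "Baseline-adjustment strategies in simulated LAZ trials: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline-adjustment strategies in simulated LAZ trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lazsim)
```

## The data-generating model

A simulated trial enrols `n` children and measures length-for-age z-score
(LAZ) at ages 0 (baseline), 6, 12, 18 and 24 months. The joint
distribution of the five measurements is multivariate normal,
parameterized by a mean and SD per timepoint and a correlation matrix
between timepoints (`laz_population()`). The defaults describe a
progressively faltering birth-cohort population:

```{r}
laz_population()
```

Three features of this parameterization drive everything else:

* mean LAZ falls from −1.10 at birth to −2.03 at 24 months (growth
  faltering);
* per-timepoint SDs are roughly constant (0.93–1.03 z-score units);
* the correlation between baseline and a later measurement decays with the
  gap: 0.61 at 6 months but 0.44 at 24 months. The value 0.5 is the
  classical pivot at which the change score and the endpoint-only analysis
  swap precision rankings, and the default correlations straddle it.

The intervention is an additive, deterministic shift of mean LAZ in the
intervention arm that accumulates by +0.05 per 6 months
(`effect_profile()`), so the cumulative effect is 0.05/0.10/0.15/0.20 at
6/12/18/24 months — an effect size representative of large nutrition and
WASH efficacy trials. There is no effect heterogeneity and no effect on
the variance: the model is a pure mean shift, which is what the five
estimators under study all target.

Arm allocation is an independent Bernoulli draw per child
(`allocation_rule()`). The balanced rule uses probability 0.5. The
imbalanced rule makes the probability linear in baseline LAZ,
`P(intervention) = 0.47 − 0.03·LAZ0`, mimicking a failed or subverted
randomization in which shorter children preferentially end up in the
intervention arm. Under the default baseline distribution this induces an
expected baseline difference of

```{r}
expected_baseline_imbalance(laz_population(), allocation_rule("imbalanced"))
```

i.e. the intervention arm starts about 0.13 LAZ shorter. A reversed
variant (`"imbalanced_reversed"`, slope +0.03) puts the imbalance in the
same direction as the effect; it flips the sign of the induced biases.
The allocation probability is clamped to [0.01, 0.99] before the draw —
a numerical guard only, since the linear form stays inside (0, 1) for any
baseline within ±17 SD of its mean. Allocation uses the pre-effect
baseline, which is identical to the observed baseline because the effect
at baseline is constrained to zero.

## The five estimators

All five methods are ordinary least squares with an intercept; `β1`, the
coefficient of the arm indicator, is the estimate of the intervention
effect at the chosen endpoint:

* **FINAL** — endpoint on arm;
* **ADJUST** — endpoint on arm + baseline (ANCOVA);
* **DELTA** — (endpoint − baseline) on arm;
* **DELTA+ADJUST** — (endpoint − baseline) on arm + baseline;
* **RESIDUALS** — endpoint on baseline alone, then those residuals on arm.

Inference is t-based: `SE` from the unbiased residual-variance estimator,
95% CI as `β1 ± t(df, 0.975)·SE`. At the sample sizes of interest
(n ≥ 100) the difference from normal-based intervals is negligible, but t
is the OLS convention. The RESIDUALS second stage deliberately uses the
naive OLS standard error of the second regression, with no correction for
the estimated first stage — that is how the two-step recipe is used in
practice, and its inferential consequences are part of what the
simulations measure.

Two algebraic facts anchor the test suite. DELTA+ADJUST is an exact
reparameterization of ADJUST: subtracting the baseline from both sides
leaves `β1` and its SE untouched and lowers the baseline coefficient by
exactly 1 (asserted per trial at 10⁻¹⁰). RESIDUALS coincides with ADJUST
exactly only when arm and baseline are sample-orthogonal; under random
allocation the two agree to the two-decimal resolution at which
operating characteristics are reported, and the simulations confirm
identical summaries after rounding.

## Operating characteristics

For each (scenario, n, timepoint, method) cell, `run_grid()` simulates
`n_replicates` trials and reports: the median `β1` with the 2.5th/97.5th
percentiles of its replicate distribution (the 95% uncertainty interval),
bias defined as median minus the true simulated effect, the mean SE, power
(fraction of two-sided p < α, with α = 0.05 by default; the sign of the
estimate is not checked), and coverage (fraction of CIs containing the
truth). The median, rather than the mean, defines bias; the sampling
distributions here are symmetric, so the closed-form mean-bias companions
remain comparable. Percentiles use the default linear-interpolation
convention (`quantile` type 7); at 1000 replicates the convention shifts
the UI bounds by well under 0.001. Each trial also yields the
baseline-imbalance diagnostic: OLS of baseline LAZ on arm, whose slope is
the arm difference in mean baseline LAZ and whose two-sided p flags a
"significant imbalance" at p < 0.05.

All methods and timepoints are fit to the *same* simulated trials
(pairing), as a real analyst would apply competing analyses to one
dataset; this also removes between-method Monte Carlo noise from
comparisons, and makes the ADJUST/DELTA+ADJUST identity hold row by row
in every results table.

## Analytic companions

The closed-form module exists to validate the simulator, not to replace
it. For a normal baseline under the linear allocation rule, the expected
arm difference at baseline is exactly `b·σ0² / (p̄(1 − p̄))` with
`p̄ = a + b·μ0`. Propagating that difference through the population
regression slope of endpoint on baseline, `β_slope = ρ·σi/σ0`, gives the
first-order expected biases: `β_slope·Δ0` for FINAL, `(β_slope − 1)·Δ0`
for DELTA, and 0 for the adjusted methods (for RESIDUALS, 0 to first
order; the neglected terms are of order `Δ0²/σ0²` and `δ·Δ0/σ0²`, below
0.001 here). The per-arm residual variances are the classical factors
`σi²` (FINAL), `σi² + σ0² − 2ρσiσ0` (DELTA) and `σi²(1 − ρ²)` (adjusted),
and approximate power is the two-tailed normal form
`Φ(λ − z) + Φ(−λ − z)` with `λ = |δ|/√(4·factor/n)`, which returns
exactly α under the null. The test suite requires the simulated biases to
track the closed forms within 0.015 and mean SE²·(n/4) to recover the
variance factors within 5%.

## Sample-size search

`find_sample_size_for_power()` simulates the power curve on an enrolment
grid (default step 100 up to 12,000), applies isotonic (monotone
non-decreasing) regression, and returns the smallest grid value whose
smoothed power reaches the target (default 0.80), or `NA` when the cap is
reached. Isotonic smoothing was chosen over a scatterplot smoother
because it is deterministic, has no bandwidth parameter, and respects the
monotonicity that power-vs-n must satisfy, making the crossing rule a
well-defined pass/fail criterion rather than a visual read-off. Odd
enrolments are split by the Bernoulli allocation itself — no forced equal
arms, since randomization is per child.

## Reproducibility

An experiment carries one master seed. Each replicate's seed derives from
the master seed and the cell coordinates (scenario, n, replicate) through
a fixed mixing recurrence modulo 2³¹ − 19, so any single trial can be
regenerated in isolation and cell results do not depend on the order in
which cells are run (asserted in the tests by permuting the grid). Table 1
-style population moments are fixed constants of the configuration, not
redrawn per trial: redrawing them would make the reported operating
characteristics irreproducible and conflate parameter uncertainty with
sampling variability.

## Problem sizes used in the shipped checks

The packaged test suite and the reproduction script run the study at its
native scale: 1000 replicates per cell for operating characteristics at
n = 1000, a 100–2000 enrolment grid at 1000 replicates for the 18-month
sample-size requirements, 2000 replicates for null-calibration bands, and
10⁶-draw checks of the generator's moments. Monte Carlo error at these
sizes is about ±0.013 (binomial SE) for a power near 0.8 and about
0.002–0.004 for median estimates.

## What the generator does and does not emulate

The simulations inherit every assumption of the generator: joint
normality, a common covariance in both arms, a homogeneous additive
effect, complete follow-up, and exact per-child Bernoulli allocation.
Real growth trials feature dropout, missed visits, measurement error,
cluster randomization, floor effects in severely malnourished
populations, and effect modification — none of which are modelled.
Passing results therefore demonstrate the relative behaviour of the five
estimators under the idealized conditions in which their algebraic
properties are cleanly separable, not the absolute performance to expect
in a field trial. Likewise the imbalanced scenario models one specific
selection mechanism (linear in baseline LAZ); other confounding
structures can produce biases that baseline adjustment alone does not
remove. Extensions deliberately out of scope: mixed-effects models over
multiple post-randomization endpoints, robust/sandwich standard errors,
and non-normal outcome distributions.

## Degenerate inputs and numerical notes

Correlation matrices are validated for symmetry, unit diagonal and
positive semi-definiteness (eigenvalue tolerance −10⁻⁸) both on entry and
after assembly into a covariance, with the offending eigenvalue reported.
Rank-deficient design matrices (e.g. a constant baseline) abort the fit
naming the collinear column rather than silently dropping it. Trials with
a single arm, fewer than two children, or a nonzero baseline effect are
rejected with explicit errors. Null-effect sample-size searches are
refused, since power never systematically exceeds α.
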