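# lazsim

Monte Carlo evaluation of baseline-adjustment strategies in child linear
growth trials.

## The problem

Randomized controlled trials of interventions against childhood stunting
usually measure length-for-age z-score (LAZ) at enrolment (baseline) and
again at follow-up visits. The statistical analysis plan then has to choose
how the baseline measurement enters the primary analysis. With `y_i` the
endpoint LAZ, `y_0` the baseline and `x` the intervention indicator, the
common options are:

| Method       | Regression                         |
|--------------|------------------------------------|
| FINAL        | `y_i = β0 + β1 x`                  |
| ADJUST       | `y_i = β0 + β1 x + β2 y_0` (ANCOVA)|
| DELTA        | `y_i − y_0 = β0 + β1 x`            |
| DELTA+ADJUST | `y_i − y_0 = β0 + β1 x + β2 y_0`   |
| RESIDUALS    | `y_i = β0 + β2 y_0`, then its residuals `= β3 + β1 x` |

`β1` is the intervention effect. The choice is consequential: DELTA forces
the baseline coefficient to 1 while ADJUST estimates it from the data, so
the two disagree whenever the arms differ at baseline (Lord's paradox), and
the power of FINAL vs DELTA flips with the baseline–endpoint correlation.

`lazsim` quantifies these trade-offs by simulation. Trials are drawn from a
multivariate normal growth model (means, SDs and inter-timepoint
correlations of a faltering birth-cohort population at 0, 6, 12, 18 and 24
months), with an additive cumulative intervention effect (default +0.05 LAZ
per 6 months, i.e. 0.20 at 24 months) and Bernoulli arm allocation that is
either balanced (probability 0.5) or dependent on baseline LAZ
(`P(intervention) = 0.47 − 0.03·LAZ0`), which induces a mean baseline
imbalance of about −0.13 LAZ in the intervention arm. For every method ×
timepoint × sample-size cell the package reports the median effect
estimate with its 95% uncertainty interval, bias, mean standard error,
power and coverage, alongside closed-form analytic companions (expected
imbalance under linear selection, first-order estimator bias, residual
variance factors and normal-approximation power) used to validate the
Monte Carlo engine.

## Worked example

```r
library(lazsim)

trial <- simulate_trial(n = 1000, seed = 42, rule = allocation_rule("imbalanced"))
summary(trial)
#> Two-arm LAZ trial, 1000 children ( 521 intervention )
#> mean LAZ by arm:
#>               laz_0  laz_6 laz_12 laz_18 laz_24
#> control      -1.021 -1.145 -1.642 -1.922 -2.002
#> intervention -1.147 -1.135 -1.542 -1.772 -1.811
#> baseline difference (intervention - control): -0.125 LAZ

estimate_effect(trial, 24, "ADJUST")
#> ADJUST estimate at 24 months (n = 1000):
#>   beta1 = 0.2425 (SE 0.0535), 95% CI [0.1375, 0.3474], p = 6.49e-06
```

In this single trial the allocation rule has made the intervention arm
0.125 LAZ shorter at baseline. The true simulated effect at 24 months is
0.20: ADJUST lands near it, while on the same trial FINAL gives 0.19 and
DELTA 0.32 — the baseline imbalance pulls the unadjusted estimators in
opposite directions.

Operating characteristics over many replicates:

```r
cfg <- experiment_config(scenarios = "imbalanced", n_grid = 1000,
                         n_replicates = 200, master_seed = 42,
                         timepoints_of_interest = 24)
rounded_view(run_grid(cfg))
#>     scenario    n timepoint       method true_effect median_estimate ui_low ui_high  bias mean_se power coverage ...
#> 1 imbalanced 1000        24        FINAL         0.2            0.15   0.04    0.26 -0.05    0.06  0.74     0.90
#> 2 imbalanced 1000        24       ADJUST         0.2            0.20   0.10    0.30  0.00    0.05  0.97     0.95
#> 3 imbalanced 1000        24        DELTA         0.2            0.28   0.15    0.40  0.08    0.07  0.99     0.73
#> 4 imbalanced 1000        24 DELTA_ADJUST         0.2            0.20   0.10    0.30  0.00    0.05  0.97     0.95
#> 5 imbalanced 1000        24    RESIDUALS         0.2            0.20   0.10    0.30  0.00    0.05  0.97     0.95
```

Read: under the imbalanced allocation FINAL is biased downward (−0.05) and
under-covers (0.90), DELTA is biased upward (+0.08) with coverage 0.73,
while the three baseline-adjusted methods are unbiased with nominal
coverage and the smallest standard errors. Sample sizes for a power
target come from the same machinery:

```r
cfg <- experiment_config(scenarios = "balanced", n_replicates = 1000,
                         master_seed = 1, n_search_max = 2000)
find_sample_size_for_power(cfg, "balanced", c("FINAL", "DELTA", "ADJUST"), 18)
#> FINAL  DELTA ADJUST
#>  1300   1500    900
```

ADJUST reaches 80% power for the 0.15-LAZ 18-month effect with roughly 900
children, DELTA needs about two thirds more.

A thin command-line driver is provided in `inst/scripts/simstudy.R`
(`grid`, `samplesize` and `oracle` tasks, YAML-configurable via
`read_config_yaml()`), and the methods vignette
(`vignettes/baseline-adjustment.Rmd`) documents the model, its
assumptions and the numerical choices.

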