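Package: lazsim
Title: Monte Carlo Evaluation of Baseline-Adjustment Strategies in Child
    Growth Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two-arm randomized controlled trials with a
    length-for-age z-score (LAZ) endpoint measured at baseline and at
    6, 12, 18 and 24 months, and compares five regression strategies for
    handling the baseline measurement: endpoint only (FINAL), ANCOVA
    (ADJUST), change score (DELTA), change score with baseline adjustment
    (DELTA+ADJUST), and the two-step residuals approach (RESIDUALS).
    Trials are drawn from a multivariate normal growth model with an
    additive cumulative intervention effect; arm allocation is either
    balanced or made dependent on baseline LAZ to induce a controlled
    baseline imbalance.  The package computes operating characteristics
    (median estimate, 95% uncertainty interval, bias, mean standard
    error, power, coverage), closed-form analytic companions for
    validation, and power-based sample-size requirements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
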