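Package: powersim
Title: Monte Carlo Power Estimation for Cluster-Randomized and
    Multi-Level Factorial Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates statistical power for individual-, cluster-, and
    multi-level factorial randomized designs by simulation. Outcomes are
    generated from mixed-effects data-generating models (continuous,
    binary, and two-treatment factorial with village and child random
    effects), each simulated replicate is analyzed with cluster-robust
    sandwich regression, and the empirical rejection rate estimates
    power. Includes the analytic benchmark formula for parallel
    cluster-randomized trials, null-simulation calibration diagnostics
    with a bootstrapped Kolmogorov-Smirnov uniformity test,
    variance-component estimation from long-format training data, a
    minimum-detectable-effect search, and generators for synthetic
    training datasets that emulate field anthropometry cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
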