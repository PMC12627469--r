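Package: paincontrol
Title: Bayesian Expectation-Integration Models of Controllable and
    Predictable Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heat-pain rating experiments in which
    stimulus intensity is controllable, predictable, or unpredictable.
    Implements truncated-normal Bayesian observer models of pain ratings
    (mean-shift and precision-change variants with fixed or dynamic
    unpredictable-condition priors), hierarchical MCMC fitting via JAGS,
    highest-posterior-density intervals, leave-one-out model comparison by
    Pareto-smoothed importance sampling and a robust mixture estimator with
    an exact refit oracle, simulation-based parameter recovery, Bayesian
    mixed-effects models of ratings and rating variability, a synthetic
    trial generator emulating the three-condition task, and a
    simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
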