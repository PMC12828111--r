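Package: dosesched
Title: Biomarker-Stratified Bayesian Dose-Schedule Optimization for
    Immunotherapy Phase I/II Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation engine for Bayesian phase I/II
    immunotherapy trials that jointly model a continuous immune response
    (plateau dose-response), binary dose-limiting toxicity (logistic), and
    ordinal tumor response (Bayesian dynamic models with a
    proportional-odds shift), stratified by a binary biomarker subgroup.
    Provides Metropolis-within-Gibbs posterior sampling, utility-based
    risk-benefit scoring, two-stage adaptive dose-schedule allocation
    (Beta-Binomial toxicity screening followed by utility-weighted
    adaptive randomization), whole-trial simulation from Gumbel-copula
    truth scenarios, and replicated operating-characteristics summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
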