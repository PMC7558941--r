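Package: popsse
Title: Stochastic Simulation and Estimation for Population PK Sampling Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate how the blood-sampling period (first dose,
    fourth dose, or both) affects the accuracy and precision of population
    pharmacokinetic parameter estimates. Provides a closed-form
    two-compartment intravenous-infusion model with multiple-dose
    superposition, simulation of virtual cohorts with exponential
    between-subject variability and proportional residual error, a
    first-order conditional estimation (with interaction) and Laplace
    nonlinear mixed-effects estimator, and a stochastic
    simulation-and-estimation engine reporting relative bias and relative
    root-mean-square error per scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
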