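Package: mixlearn
Title: Mixture Learning Models for Responses and Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-mode (engaged/disengaged) mixture hidden-Markov
    diagnostic classification model to longitudinal learner logs of item
    responses and response times. Engaged learners answer under a DINA
    measurement model with log-normal response times and acquire skills over
    time through a higher-order logistic transition model; disengaged
    learners rapid-guess at a flat accuracy with their own log-normal latency
    law and frozen skill profiles. Includes a simulator for the full design,
    a Metropolis-Hastings-within-Gibbs posterior sampler with block updates
    of frozen attribute segments, convergence and fit diagnostics
    (Gelman-Rubin PSRF, joint DIC, posterior predictive checks), and a
    parameter-recovery evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
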