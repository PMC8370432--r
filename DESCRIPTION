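Package: microdcm
Title: Conductance-Based Dynamic Causal Modelling of Auditory Event-Related
    Fields with Hierarchical Bayesian Group Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and inverts a conductance-based six-population cortical
    microcircuit network that generates source-level event-related fields in a
    roving auditory oddball paradigm. Single-subject models are fitted by
    variational Laplace (Gauss-Newton free-energy ascent), redundant parameters
    are removed by Bayesian model reduction, and group, drug and
    neurotransmitter-covariate effects are estimated with multi-level
    parametric empirical Bayes, including third-level comparisons of group
    models and free-energy comparison of covariate designs. A synthetic-cohort
    generator with injectable group, drug, interaction and GABA-slope effects
    makes every stage of the pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
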