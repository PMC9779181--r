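Package: hrvo2
Title: Bayesian Hierarchical Analysis of the Heart Rate-Oxygen Uptake
    Relationship During Graded Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate whether percent heart-rate reserve (%HRR)
    tracks percent oxygen-uptake reserve (%VO2R) or percent maximal oxygen
    uptake (%VO2max) along the line of identity during graded treadmill and
    cycle exercise. Provides a synthetic-cohort generator with the
    hierarchical linear structure the analysis assumes, extraction rules for
    resting and maximal cardiorespiratory values, a Gibbs sampler for the
    Bayesian random-intercept/random-slope model of %HRR on %VO2,
    convergence diagnostics (potential scale reduction factor,
    Raftery-Lewis dependence factor, spectral effective sample size),
    Bayesian two-group mean comparisons, and posterior reporting: identity
    line tests, sex and exercise-mode contrasts, and modal %HRR predictions
    with credible intervals at prescribed exercise intensities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
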