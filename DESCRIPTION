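Package: hgfcue
Title: Hierarchical Gaussian Filter Modelling of Dual-Contingency Cueing Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and trial-by-trial Bayesian modelling of behaviour in
    probabilistic cueing tasks with two independent cue-target contingencies
    (spatial and temporal) whose validity drifts under changing volatility.
    Provides a seeded task and schedule generator, binary Hierarchical
    Gaussian Filter observer models (2- and 3-level, with context-specific or
    nonspecific learning rates) and a Rescorla-Wagner baseline,
    relevance-weighted logistic response models, MAP parameter estimation
    with a Laplace approximation to log model evidence, random-effects
    Bayesian model selection with protected exceedance probabilities, and
    behavioural condition summaries plus trial-wise prediction and
    precision-weighted prediction-error regressors for downstream GLMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
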