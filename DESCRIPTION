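Package: thermopop
Title: Temperature Dependence of Population Growth Parameters from
    Abundance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates temperature-stratified abundance time series from a
    stochastic logistic birth-death process whose demographic rates follow
    the Arrhenius equation, and estimates the activation energy of
    population growth rate and carrying capacity. Implements a family of
    indirect estimators (per-temperature fits followed by weighted
    Arrhenius regression) and direct estimators (joint multi-temperature
    fits with activation energy as an explicit parameter), using either a
    phenomenological deterministic likelihood or Gaussian likelihoods built
    from the moment (diffusion) approximation of the birth-death process,
    with an optional correction for Poisson sampling error. A factorial
    design-evaluation layer quantifies estimator accuracy and precision
    across experimental designs and ranks the design factors with
    regression trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
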