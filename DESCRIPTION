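Package: durddm
Title: Diffusion Decision Models for Duration Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trial-level diffusion decision models for two-interval duration
    discrimination in which drift rates and starting points are driven by
    internal-reference updating and sensation weighting. Provides the Wiener
    first-passage-time likelihood and a stochastic simulator, a synthetic
    experiment generator for the classical standard/comparison paradigm,
    exponentially weighted moving-average screening of fast guesses,
    hierarchical Bayesian estimation with convergence diagnostics,
    Pareto-smoothed importance-sampling approximate leave-one-out model
    comparison, per-participant psychometric functions with Type A and
    Type B context-effect estimation, and posterior predictive checks of
    choice proportions and response-time quantiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
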