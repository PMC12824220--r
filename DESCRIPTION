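Package: accumimic
Title: Sequential-Sampling Model Mimicry for Deadlined Value-Based Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and fitting tools for sequential-sampling models of
    deadlined value-based choice: drift diffusion models with static or
    linearly collapsing decision bounds whose parameters are trial-level
    regressions on option-value regressors, and a rectified leaky competing
    accumulator with collapsing bound. Model log-likelihoods are estimated by
    inverse binomial sampling over stratified reaction-time decile categories
    and maximised with noise-tolerant derivative-free optimisation. Includes
    quantile-based BIC model comparison with bootstrap confidence intervals,
    a synthetic task generator for two-fractal bundle choices under a
    response deadline, and pipelines for model recovery, parameter recovery,
    and model-mimicry experiments in which control-free accumulator dynamics
    masquerade as value-dependent threshold control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
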