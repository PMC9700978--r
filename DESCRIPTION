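Package: bucpsced
Title: Bayesian Unknown Change-Point Models for Single-Case AB Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Bayesian unknown change-point (BUCP) model to
    single-case experimental design (SCED) AB time series: two phase
    levels, AR(1) autocorrelated normal errors, and a discrete change
    point estimated jointly with the other parameters by multi-chain
    Gibbs/Metropolis MCMC. Includes a data model for the 13-item ABC
    Dementia Scale (ABC-DS) with ADL, BPSD and cognitive subscales, a
    synthetic AB-series generator with known truth, Gelman-Rubin PSRF
    convergence diagnostics, a standardized-mean-difference effect-size
    posterior, credible-interval significance decision rules, and
    brute-force reference posteriors for validating the sampler.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
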