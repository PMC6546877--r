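Package: plaidobs
Title: Bayesian Causal-Inference Observer Models for Bistable Plaid Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits hierarchical Bayesian causal-inference
    observer models of bistable plaid-motion perception, in which an
    ambiguous moving stimulus is seen either as one coherent pattern or as
    two transparent surfaces. Provides the circular direction-space
    likelihood and conditional prior machinery (model variants M1-M4), a
    two-stage Monte-Carlo trial simulator, psychometric-function fitting
    with bootstrap, perceptual bias and stability-index statistics,
    Kullback-Leibler model fitting with AIC comparison, a synthetic-observer
    cohort generator emulating a density x regularity psychophysics design,
    and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
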