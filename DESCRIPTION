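Package: gradedRT
Title: Joint Modeling of Graded Item Responses and Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration and scoring tools for multidimensional graded
    response models coupled to lognormal item response-time models with a
    cross-relation between latent ability and log response time and optional
    interviewer covariates.  Supports marginal maximum likelihood estimation
    via an EM algorithm with the latent speed factor integrated analytically,
    concurrent calibration of multiple data-collection batches through anchor
    items, fixed-parameter calibration, expected a posteriori scoring with
    posterior standard errors, response-time preprocessing (trimming,
    respondent exclusion, log-normality diagnostics, sparse-category
    collapsing), and a synthetic-data generator for interviewer-administered
    multi-batch item banks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mvtnorm,
    statmod,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    numDeriv
Config/testthat/edition: 3
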