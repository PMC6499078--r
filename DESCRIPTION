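Package: sumaerr
Title: Shared and Unshared Multiplicative and Additive Exposure
    Measurement Error from Prediction Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the four components of exposure measurement error
    (shared multiplicative, unshared multiplicative, shared additive,
    unshared additive) in ensemble-based exposure prediction models by
    treating the ensemble members as realizations from a dosimetry
    system.  Components are estimated by ordinary least squares
    regression of across-ensemble pairwise covariances on products of
    prediction means, and of across-ensemble variances on squared means.
    Predictions carrying high shared multiplicative measurement error
    are identified by dichotomizing mean pairwise covariances, and their
    spatial and temporal structure is modelled with a logistic
    generalized additive model with a bivariate smooth of location,
    including grid prediction of odds-ratio surfaces, pointwise
    significance flagging, and iterative covariate selection.  A
    synthetic-data generator with configurable error structure supports
    parameter-recovery testing throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
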