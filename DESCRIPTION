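Package: trendvcm
Title: Time-Varying Coefficient Models for Behaviour Risk Factor Surveillance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits logistic (and Gaussian) varying coefficient models in which
    selected covariate effects are smooth functions of calendar time, estimated
    by P-splines: B-spline bases with difference penalties, penalized iteratively
    reweighted least squares (Fisher scoring), and GCV or approximate REML
    smoothing-parameter selection. Includes the two-stage model-building
    procedure used in surveillance trend analysis (likelihood-ratio screening of
    each covariate for time-varying effects, then stepwise forward selection by
    residual deviance explained), odds-ratio-over-time curves with Bayesian
    posterior bands, and a generator of synthetic repeated cross-sectional
    surveillance data with known constant and time-varying effects for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
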