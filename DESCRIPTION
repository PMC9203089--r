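Package: biliphone
Title: Smartphone Transcutaneous Bilirubinometry: Photon Transport,
    Capture Calibration, and Arc-ROI Gamma Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational stack for a mobile-phone transcutaneous
    bilirubinometer. Provides a weighted-photon Monte-Carlo model of
    spatially offset diffuse reflectance from layered neonatal skin (with
    an analytic diffusion-theory cross-check) for adapter geometry design,
    a raw-capture calibration pipeline (demosaicing, outlier-frame
    rejection, dark-frame subtraction and reflectance-standard
    normalization), a two-stage estimator of total serum bilirubin from
    filtered RGB reflectance images (bounded pattern-search optimization
    of arc-shaped regions of interest feeding a gamma generalized linear
    model under stratified cross-validation), Bland-Altman and RMSE
    agreement statistics, and a synthetic-cohort generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
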