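Package: longicv
Title: Cross-Validated Prediction of IQ Change from Longitudinal Grey-Matter Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-step cross-validated analysis of longitudinal voxel-based
    morphometry: a mass-univariate general linear model relates within-subject
    change in verbal and performance IQ to change in grey-matter density
    (region selection with permutation-based family-wise-error control and
    cluster-extent thresholding), and an out-of-sample regression predicts IQ
    change from density change at the selected peak. Both exhaustive
    Leave-One-Out and repeated stratified split-half schemes are provided,
    together with a synthetic-cohort generator with planted regional effects
    so that selection, correction and prediction can be validated against a
    known ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
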