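Package: dyadsync
Title: Estimating Dyadic Movement Synchrony, Estimation Error, and fNIRS
    Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying movement synchrony in dyads from pose
    keypoint time series (pose-matrix similarity and sample-entropy
    complexity), modelling observers' synchrony estimation error with
    hierarchical Bayesian regressions, and estimating evoked haemodynamic
    responses from two-wavelength fNIRS recordings (optical density
    conversion, motion-artifact repair, modified Beer-Lambert law,
    short-channel regression, AR(1) GLM, region-of-interest aggregation).
    Includes synthetic-data generators for coupled leader-follower
    kinematics, observer estimation behaviour, and forward-modelled fNIRS
    recordings with known ground truth, so the full analysis pipeline can
    be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
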