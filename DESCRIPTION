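Package: rfilm
Title: Residual Plastic Film Segmentation and Pollution Evaluation from UAV
    Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates residual plastic-film pollution on the surface of
    pre-sowing cotton fields from low-altitude UAV RGB imagery.  Implements a
    slimmed U-shaped encoder-decoder segmentation network whose down-sampling
    stages use multiscale inception blocks followed by 1x1 channel reduction,
    together with the full training recipe (random crop, flips, brightness
    jitter; per-pixel cross-entropy; Adam; best-checkpoint selection),
    per-pixel confusion-matrix metrics (accuracy, precision, recall, F1,
    mean IoU), and an areal coverage-rate pollution statistic with regression
    validation of predicted against true coverage.  A synthetic scene
    generator with exact ground-truth masks emulates film fragments over
    textured soil with straw and clod confusers, weather-dependent specular
    highlights, and flight-height blur/scale degradation, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
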