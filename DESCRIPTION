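Package: cryograder
Title: Quality Scoring and Iterative Curation of Cryo-EM 2D Class Averages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the quality of single-particle cryo-EM 2D class averages
    with a residual convolutional neural network that fuses image content with
    six physical metadata features (pixel size, FRC resolution estimate,
    relative class distribution, and three particle-mass deviation features
    derived from a pixel-intensity mass estimator). Includes MRC2014 and STAR
    file handling, Fourier-space image canonicalization, a fully seeded CPU
    training loop, an iterative score-gated particle selection workflow with a
    pluggable 2D-classification backend, and a synthetic-data generator for
    calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
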