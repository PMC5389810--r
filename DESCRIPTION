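Package: soarclass
Title: Supervised Classification of Soaring-Bird Flight Behaviour from
    Tri-Axial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw tri-axial accelerometry from large soaring
    birds into behaviour classifications.  Provides sequential change-point
    segmentation of the acceleration stream (generalized likelihood-ratio
    monitor with Monte-Carlo calibrated thresholds), per-segment summary
    statistics including overall dynamic body acceleration (ODBA),
    ethogram-based labelling of segments from annotated time intervals,
    optimised random-forest and K-nearest-neighbour classifiers with
    confusion-matrix metrics and repeated k-fold cross-validation, a
    sampling-frequency subsampling study, and a synthetic accelerometry
    generator with known behaviour boundaries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    caret,
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
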