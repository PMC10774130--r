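Package: facekit
Title: Orofacial Keypoint Tracking and Behavioral Encoding Models of Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mouse orofacial behavior from videos and for
    relating behavior to large-scale neural recordings. Provides a compact
    U-Net-style keypoint tracker trained on heatmaps and location-refinement
    maps with subpixel decoding, quality-control filtering of keypoint traces,
    an autoregressive estimator of per-keypoint predictability timescales, a
    deep network encoding model of population activity from behavior with
    peer-prediction normalization of explained variance, reduced-rank
    regression baselines, scaled k-means clustering of neurons with a spatial
    locality index, and discrete Gaussian-emission hidden Markov models over
    deep behavioral features fit by direct gradient ascent on the exact
    log-likelihood, together with a suite of state-transition statistics.
    Synthetic-data generators provide statistically structured fixtures for
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
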