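Package: actiseg
Title: Adaptive-Window Human Activity Recognition from Wearable Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Human activity recognition from triaxial accelerometer and
    gyroscope streams using adaptive windows. Sensor streams are aligned
    onto a common sampling grid, denoised with median and zero-phase
    Butterworth filters, segmented either with greedy Gaussian segmentation
    (a covariance-regularized maximum-likelihood changepoint method) or
    with fixed-size sliding windows, summarized into 168 time- and
    frequency-domain statistical features per segment, and classified with
    gradient-boosted trees. Segment predictions are broadcast to per-sample
    (instantaneous) predictions so that segmentation schemes can be
    compared on a common denominator. A synthetic-data simulator generates
    labeled multichannel activity streams with controllable bout structure
    and acquisition artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
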