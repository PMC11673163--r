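Package: siftstab
Title: Keypoint Stability and Threshold Tuning for 2D Tomographic Image
    Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A from-scratch difference-of-Gaussians (SIFT-style) keypoint
    detector for 2D grayscale slices with the contrast and eigenvalue-ratio
    thresholds exposed as first-class parameters, a randomized affine
    transform laboratory, a per-keypoint stability statistic linking
    keypoint properties to re-detectability under known transforms, a
    4-degree-of-freedom feature-based registration pipeline with mutual
    nearest-neighbor matching, and a threshold-sweep benchmark scoring
    good-match rates, difference-image RMSE, and normalized keypoint
    counts. Includes a synthetic cone-beam CT phantom generator so the
    whole analysis runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
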