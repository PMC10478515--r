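Package: speckfew
Title: Few-Shot Metric-Learning Classification of X-Ray Speckle Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and few-shot classification of coherent-diffraction
    (speckle) patterns from X-ray single-particle imaging experiments.
    Provides a self-contained flat-Ewald speckle simulator (single-hit,
    multi-hit and non-sample-hit classes with photon shot noise, fluence
    jitter, beam-stop and panel-gap masks), leakage-safe data augmentation,
    a convolutional embedding network trained on the unit hypersphere with
    a triplet loss and semi-hard negative mining, N-way X-shot
    query-against-support classification, and evaluation protocols for
    photon-fluence scans and missing-detector-area robustness against a
    probability-threshold binary baseline.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
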