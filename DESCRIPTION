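Package: fedseg
Title: Federated Self-Configuring Medical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale federated learning framework for medical image
    segmentation with self-configuring U-Nets. Implements federated dataset
    fingerprint extraction (concatenation of per-center fingerprints into a
    global fingerprint so all sites derive identical training plans) and
    asymmetric federated averaging (aggregation of only those layers that
    share name and parameter shape across heterogeneous client
    architectures), alongside local and centralized baselines, Dice and
    95th-percentile Hausdorff distance evaluation, cross-center evaluation
    matrices, and a synthetic multi-center data generator emulating
    heterogeneity in voxel spacing, matrix size and intensity distribution.
    Clients are simulated in-process; only fingerprints and model states
    ever cross the client boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
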