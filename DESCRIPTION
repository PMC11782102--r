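Package: dpratio
Title: Duct-to-Parenchyma Ratio Morphometry for Pancreatic CT Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the cross-sectional area ratio of the main pancreatic
    duct to the pancreatic parenchyma (DP ratio) along a pancreas centerline
    estimated with Dijkstra's routing algorithm from co-registered binary
    segmentation masks, and summarises the profile by its 90th percentile
    (the 90th DP ratio), a single shape feature sensitive to both main
    pancreatic duct dilation and pancreatic parenchymal atrophy. Includes
    spacing-aware distance transforms, rotation-minimizing frames for
    perpendicular cross-section resampling, synthetic tubular phantoms with
    analytic ground-truth profiles, and cohort-level evaluation (Welch tests,
    ROC analysis, operating-point thresholds, Bonferroni-corrected group
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
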