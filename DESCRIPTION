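Package: msimfnet
Title: Multi-Scale Input and Multi-Feature Fusion Networks for
    Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Patch-based classification of hematoxylin-and-eosin stained
    histopathology images with a multi-scale input, multi-feature fusion
    convolutional network. Provides readers for BreakHis-style and
    ICIAR2018-style image trees with patient-disjoint splitting, H&E stain
    normalization, four-scale pyramid and quadrant patch extraction, a
    dense-connectivity backbone with global-average-pool taps fused into a
    single descriptor, a closed-form per-layer parameter ledger, patch-wise
    training with cross-validation and an ablation harness, three
    patch-to-image probability voting rules with malignancy-priority
    tie-breaking, evaluation metrics, and the continuity-corrected McNemar
    test for paired classifier comparison. Includes a seeded synthetic
    histology generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
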