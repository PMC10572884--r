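Package: boneseg
Title: Bone Metastasis Lesion Segmentation for Whole-Body Bone Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Training and evaluation pipeline for pixel-level segmentation of
    metastatic hotspots in two-view whole-body bone scintigraphy. Provides a
    seeded synthetic phantom generator for scan-like images, the clinical
    pre-processing chain (projection-profile body detection, cut-and-center,
    linear brightness normalization, above-knee crop, view merging),
    three-class (air background / non-metastatic tissue / metastasis) label
    construction via Otsu thresholding or negative mining, a trainable
    modified Double U-Net with SoftMax outputs, Dice and focal Tversky losses
    with background-class exclusion, pixel-level precision/sensitivity/F1
    metrics with the fold-aggregation conventions of 10-fold cross-validation
    reporting, and a cross-validation and transfer-learning harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
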