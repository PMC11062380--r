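Package: yeastvac
Title: Quantifying Yeast Vacuole Fusion and Lipophagy from Fluorescence
    and Soft X-Ray Tomography Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify starvation responses of the yeast vacuole
    from microscopy data. One branch detects single cells in two-channel
    wide-field fluorescence images with a circular Hough transform,
    extracts normalized regions of interest and classifies vacuoles as
    fully or partially fused with a small convolutional neural network
    ensemble trained by stratified cross-validation; confusion-matrix
    algebra, misclassification-corrected prevalence estimates and an
    empirical resampling test turn the raw calls into error-aware group
    comparisons. The other branch segments cell, vacuole and lipid
    droplet channels in reconstructed soft X-ray tomograms with a U-Net
    trained under a compound Dice plus top-K cross-entropy loss, applies
    a configurable post-processing menu and distance-transform watershed
    instance segmentation, and derives per-droplet 3D morphometry
    (volume, distance to the vacuole, consumption calls, surface contact)
    from closed triangle meshes. Synthetic fluorescence fields and
    tomography phantoms, including a limited-angle filtered back
    projection simulator reproducing missing-wedge artifacts, provide
    full ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
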