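Package: rpeseg
Title: Coarse-to-Fine Localization and Segmentation of Retropharyngeal
    Edema in Anisotropic Neck MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable desk-scale implementation of a coarse-to-fine deep
    learning pipeline for locating and segmenting retropharyngeal edema in
    anisotropic 3D neck MRI. Slice-wise convolutional classifiers for the
    axial, coronal and sagittal views are post-processed with moving-average
    smoothing and Youden-index thresholding to build a 3D bounding region;
    64x64 tiles sampled around the region are segmented by a compact U-Net
    trained with the soft Dice loss, reassembled into per-view 3D masks and
    fused by 2.5-dimensional majority voting. Includes a synthetic anisotropic
    neck phantom generator with ground-truth lesion masks, a compiled
    single-threaded CNN engine, five-fold cross-validation orchestration, and
    the full evaluation battery (confusion metrics, AUROC, Dice, lesion volume
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
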