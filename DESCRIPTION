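Package: hipseg
Title: Modular Hip CT Femur Segmentation with Stacked-Hourglass Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-network system for slice-wise femur segmentation in hip
    CT: a modified 2D U-Net that separates bone from soft tissue, a
    densely-connected stacked-hourglass network that segments the femur with
    intermediate deep supervision, and a per-slice classifier whose femur
    confidence gates the segmentation map. Includes Hounsfield windowing and
    mid-split/mirror augmentation, a combined Dice/cross-entropy loss,
    independent stage training followed by assembly, volumetric evaluation
    (Dice overlap, directed/symmetric Hausdorff and mean surface distance in
    millimetres), NIfTI input/output with the unsigned 12-bit CT storage
    convention, and a procedural hip-phantom generator (normal plus four
    disease-like variants) so the full pipeline is trainable and testable at
    desk scale without clinical data. The convolutional network engine is
    implemented natively on BLAS matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
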