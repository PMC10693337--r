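Package: canalseg
Title: Topology-Aware Segmentation of Tubular Structures in 3D CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for segmenting thin tubular anatomy (the mandibular
    canal in dental cone-beam CT) from 3D volumes. Provides NIfTI volume and
    mask handling, CLAHE contrast enhancement and foramen-guided volume
    cropping, a shifted-window transformer encoder with a U-shaped decoder
    and pixel-level deep-residual-convolution feature fusion, differentiable
    centerline-Dice (clDice) training losses built on soft skeletonization,
    sliding-window patch inference, pseudo-label fusion for sparsely
    annotated data, a full evaluation suite (Dice, IoU, clDice, HD95), and a
    synthetic canal-phantom generator so the whole pipeline is testable
    without clinical data. The neural network and its reverse-mode
    differentiation are implemented natively with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
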