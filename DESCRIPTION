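Package: livseg
Title: Modified U-Net Segmentation of Liver and Tumor in CT Slices with
    Class-Balanced Training
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encoder-decoder (U-Net) semantic segmentation of the liver and
    of liver lesions from axial CT slices, built around a reduced-filter
    U-Net (16 base filters doubling to 128) with batch normalization and
    dropout in the contracting path. Provides a weighted dice loss and
    binary cross-entropy for training, class balancing by removal of slices
    without target foreground, on-the-fly affine augmentation applied
    jointly to image and mask, a synthetic CT-like phantom generator with
    exact liver/tumor ground truth, and an evaluation suite (Dice, Jaccard,
    pixel accuracy, symmetric volume difference, overlap renderings). The
    network forward/backward passes and the Adam optimizer are implemented
    natively with fast C++ convolution kernels, so no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    RNifti,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
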