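Package: fundusnet
Title: Lightweight Attention-Augmented CNN for Retinal Fundus Image Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end, imbalance-aware pipeline for ten-class
    retinal fundus image classification: a compact convolutional network that
    combines depthwise separable convolutions with squeeze-and-excitation and
    global-context channel attention plus a residual block; feature-space
    SMOTE class balancing; stratified 70/15/15 splitting; on-the-fly geometric
    augmentation; Adam training with reduce-on-plateau scheduling and early
    stopping; per-class and macro classification metrics; and integrated
    Grad-CAM and Grad-CAM++ saliency maps with overlay rendering. A procedural
    synthetic-fundus generator with planted, class-specific lesions makes every
    stage testable without external image downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'architecture.R'
    'augment.R'
    'layers.R'
    'model.R'
    'cam.R'
    'dataset.R'
    'training.R'
    'evaluation.R'
    'fundusnet-package.R'
    'synthetic.R'
    'interface.R'
    'methods.R'
    'smote.R'
    'split.R'
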