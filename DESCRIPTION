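Package: polypnextlstm
Title: Video Polyp Segmentation with a Pruned ConvNext Encoder and
    Bidirectional ConvLSTM Temporal Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements PolypNextLSTM, a lightweight video polyp
    segmentation network: a pruned three-stage ConvNext-Tiny encoder, a
    bidirectional convolutional LSTM bottleneck that fuses information
    across consecutive colonoscopy frames, and a UNet-style decoder with
    skip connections. Includes the combined Dice and binary cross-entropy
    training objective, evaluation metrics (Dice, IoU, 95th-percentile
    Hausdorff distance, recall) with visual-attribute stratified
    aggregation, a SUN-SEG-style clip dataset reader with consistent
    per-window augmentation and 5-fold splitting, a synthetic clip
    generator with rule-based attribute labelling, and a seeded training
    and evaluation loop. The network runs on a small reverse-mode
    automatic differentiation engine with compiled convolution kernels,
    so every stage is testable on CPU without external model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jpeg,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
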