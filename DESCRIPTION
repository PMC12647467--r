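Package: dunet
Title: Fusion Encoder-Decoder Networks for Stem and Leaf Segmentation of Plant Branches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and trains DU-Net, a semantic-segmentation architecture that
    fuses a DeepLabV3+-style atrous-spatial-pyramid branch and a U-Net-style
    skip-decoder branch over a shared, width-scalable residual encoder, for
    pixel-wise classification of plant-branch images into background, stem and
    leaf. Includes exact parameter/model-size accounting for the architecture
    family (including the lightweight n/8 channel-scaling scheme and the
    classical U-Net baseline), pixel metrics (accuracy, per-class IoU, mIoU),
    cross-entropy and soft Dice losses, mask-consistent image augmentation,
    polygon-annotation rasterization and label-mask I/O, a synthetic
    branch-scene generator with ground truth, and a seeded CPU training engine
    with Adam, learning-rate decay and best-epoch selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
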