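Package: mtpaunet
Title: Retinal Vessel Segmentation with a Multi-Scale Transformer-Position
    Attention U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements MTPA_Unet, a serial Transformer plus convolutional
    encoder-decoder for segmenting blood vessels in retinal fundus
    photographs. The network combines multi-scale patch inputs, a modified
    spatially-reduced multi-head self-attention (TMSA), a twice-applied
    criss-cross position attention, shallow-information fusion into a
    pyramid-pooling bottleneck, and Dice-loss training. Ships the full
    preprocessing chain for fundus images (weighted channel fusion,
    normalization, contrast-limited adaptive histogram equalization, gamma
    correction), patch extraction and stitching, confusion-matrix and
    ROC/PR evaluation, a seeded synthetic fundus generator so everything is
    testable without external datasets, and a small reverse-mode automatic
    differentiation engine on which the network is built.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
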