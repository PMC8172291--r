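Package: VesselFuse
Title: Multichannel Retinal Vessel Segmentation with Matched Filters and
    an Encoder-Decoder Network
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments retinal blood vessels in fundus photographs by fusing
    three enhancement channels: morphological closing-based background
    removal, a large-scale rotated Gaussian matched-filter bank, and a
    small-scale bank, the latter two followed by an inverted double
    black-hat transform. Each channel feeds an identically shaped U-Net
    style encoder-decoder trained with a Dice plus class-weighted
    cross-entropy objective; channel probability maps are binarized with a
    local-mean adaptive threshold, fused with a pixelwise OR, and pruned of
    small 8-connected components. Includes the full evaluation suite
    (sensitivity, specificity, accuracy, balanced-accuracy AUC, Matthews
    correlation, and the connectivity-area-length score) and a
    seed-reproducible fundus phantom generator so the whole pipeline can be
    exercised without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    EBImage,
    Rcpp,
    Matrix,
    methods,
    stats,
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
biocViews: Software, Segmentation, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
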