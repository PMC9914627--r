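Package: prunet
Title: Pruned Multi-Scale Skip-Connection Networks for Biomedical Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains a family of U-shaped encoder-decoder
    segmentation networks for biomedical images: the classic UNet, UNet 3+
    with full-scale skip connections, and a pruned multi-scale variant that
    keeps only the same-level encoder, the next-deeper decoder and the
    encoder two levels shallower, optionally augmented with a convolutional
    block attention module (CBAM) in every decoder block. Includes exact
    trainable-parameter accounting with calibration of unstated
    architectural conventions against published parameter counts, the Dice
    loss and the standard pixel-overlap evaluation metrics, a reproducible
    synthetic lesion/mask generator emulating dermoscopy-, ultrasound- and
    lung-CT-like data, a 5-fold cross-validation training harness with the
    ADAM optimizer, and a command-line interface. All numerical layers
    (convolution, batch normalization, pooling, bilinear resampling,
    attention) are implemented with explicit forward and backward passes so
    that training is fully reproducible on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
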