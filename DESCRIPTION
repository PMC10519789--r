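Package: fcaenet
Title: Coordinate-Attention EfficientNet for Leaf-Disease Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and audits a family of compact convolutional
    classifiers for plant-disease images: EfficientNet-B0 and derivatives in
    which squeeze-and-excitation is replaced by a fully convolutional
    coordinate attention (directional depthwise convolutions over the full
    spatial extent), an adaptive-fusion stem mixes a max-pooled image branch
    into the backbone with learnable scalar weights, batch normalization and
    Swish may be swapped for layer normalization and exact GELU, and the
    deeper stages can be trimmed to a reduced layer plan. Includes exact
    trainable-parameter and multiply-accumulate accounting, image-folder data
    handling with online Cutout/GridMask/Random-Erasing augmentation and
    photometric robustness transforms, confusion-matrix metrics with macro
    averaging, Grad-CAM heatmaps, a warmup plus exponential-decay training
    loop, and a seeded synthetic six-class leaf-image generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    nnet,
    EBImage
Config/testthat/edition: 3
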