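Package: oedcnn
Title: Detection of Architectural Dysplastic Features in Oral Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains compact convolutional neural networks for
    recognising two architectural features of oral epithelial dysplasia --
    irregular epithelial stratification and bulbous rete ridges -- in
    haematoxylin-and-eosin histopathology patches. Provides signature-library
    construction with minority-class augmentation, YCbCr colour conversion,
    dilated (a trous) convolution blocks with batch normalisation and
    configurable global pooling (average, maximum, log-sum-exp), weighted
    cross-entropy training with a halving learning-rate schedule and
    stratified k-fold cross-validation, sliding-window whole-image detection
    with FROC-style evaluation, and a synthetic H&E-like slide generator with
    per-class ground-truth masks so the whole pipeline runs without any
    private data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
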