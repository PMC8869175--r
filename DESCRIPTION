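Package: cytosynth
Title: Class-Conditional Synthesis and Evaluation of Single-Cell Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for class-conditional synthesis of single-cell microscopy
    images with a hybrid generative adversarial network that combines a
    Wasserstein critic with gradient penalty and an auxiliary cell-type
    classifier head. Includes manifest preparation for multi-source bone
    marrow cytology datasets (cell-family merging, deduplication, stain
    normalization, stratified splitting), a synthetic toy-cell fixture
    generator, minority-class balancing synthesis, a generative image
    evaluation suite (inception score, Frechet distance, perceptual
    distance, l1/l2, PSNR, SSIM), and downstream classifier comparisons
    across original, synthetic, augmented and combined training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
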