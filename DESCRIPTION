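Package: adaptqa
Title: End-to-End Quality Assurance Analytics for Online Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale end-to-end quality assurance toolkit for online
    adaptive radiotherapy. Synthesizes randomized three-dimensional Gaussian
    deformations of a phantom CT, quantifies reproducibility of repeated
    segmentations via STAPLE consensus, Dice similarity and mean symmetric
    surface distance, evaluates adaptive-plan dose-volume constraints, and
    derives organ-specific contouring and dosimetric action levels via
    ANOVA-justified pooling and 95 percent confidence intervals. Includes a
    digital pelvis phantom and a surrogate of the adaptive segmentation and
    planning process so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
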