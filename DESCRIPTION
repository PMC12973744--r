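Package: predscape
Title: Predator-Prey Spatial Ecology: Suitability Modelling, Camera-Trap
    Density and Spatial Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for spatial predator-prey analysis in
    protected areas: validation, deduplication and grid thinning of
    multi-source species occurrence records; predictor screening with
    iterative variance-inflation-factor filtering and a Gaussian kernel
    sampling-bias layer; a from-scratch L1-penalized maximum-entropy
    species distribution model with feature expansion (linear, quadratic,
    product, hinge), AICc-based tuning over regularization multipliers and
    feature classes, cross-validated AUC evaluation, suitability
    thresholding and variable-importance diagnostics; Random Encounter
    Model density estimation from camera-trap data with parametric
    bootstrap confidence intervals and suitability-weighted population
    extrapolation; and predator-prey spatial association via seeded Mantel
    permutation tests, Schoener's D niche overlap, and a
    Pearson/Spearman correlation suite with Benjamini-Hochberg correction.
    A synthetic-data module generates landscapes, occurrence points and
    camera encounters with known ground truth so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
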