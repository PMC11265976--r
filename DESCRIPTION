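Package: antalarm
Title: Antennal-Lobe Calcium Imaging Quantification and Alarm-Behavior
    Curve Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies volumetric two-photon calcium-imaging responses in
    the ant antennal lobe (fold-change response maps, responding-glomerulus
    classification, per-glomerulus area-under-curve) and compares colony
    alarm-behavior dynamics between groups with logistic-growth fits and an
    extra sum-of-squares F test. Includes per-plane deinterleaving and
    phase-correlation image stabilization, readers and writers for TIFF
    movies, ROI sets and tracking tables, and a seeded synthetic-data
    generator that emulates the acquisition and the colony assay so every
    stage can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    hdf5r,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
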