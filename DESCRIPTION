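Package: panoptes
Title: Multi-Resolution Convolutional Classification of Whole-Slide
    Histopathology Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for weakly supervised classification of
    pyramidal whole-slide images. Cuts slides into co-registered tile sets at
    2.5x, 5x and 10x equivalent magnification, filters background and
    contaminant tiles, applies structure-preserving (Vahadane-style) stain
    normalization, trains multi-branch convolutional networks of the Panoptes
    family alongside single-resolution baselines with a
    validate/checkpoint/early-stop schedule, aggregates tile predictions to
    per-patient scores, and reports AUROC/AUPR/accuracy with bootstrap
    confidence intervals, rank-sum and resampled t-test comparisons,
    multi-model POLE score composition, tSNE feature embeddings and
    whole-slide prediction heatmaps. Ships a synthetic pyramidal-slide
    generator with scale-specific class signal so every stage is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    cluster,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
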