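Package: ldlscreen
Title: RNAi Screen Hit Calling, TIRF Fusion-Event Detection and
    Ligand-Binding Models for LDL Uptake Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative procedures behind a genome-wide RNAi screen for
    LDL uptake in endothelial cells and its follow-up assays: per-plate
    robust z-score normalization with Z'-factor quality control and hit
    calling, the multi-stage siRNA deconvolution and specificity filter
    cascade, detection and classification of DiI-LDL vesicle fusion
    (transcytosis) events in TIRF time-lapse movies, Pearson and Manders
    colocalization statistics, and ligand-binding model fitting
    (one-site saturation binding and single-cycle surface plasmon
    resonance 1:1 kinetics with double referencing and competition
    analysis). Synthetic-data generators with planted ground truth stand
    in for the study's raw images and plates so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
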