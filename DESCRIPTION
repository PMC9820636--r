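Package: colonyqc
Title: Quality Control of Pluripotent Stem-Cell Colony Images with
    Small VGG-Family Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated morphology-based quality control for phase-contrast
    images of human pluripotent stem-cell (hPSC) colonies.  Provides a
    synthetic colony-image generator with ground-truth good/bad phenotype
    labels, the classical image preprocessing operators (grayscale
    conversion, min-max normalization, binarization, histogram
    equalization), dihedral and random-crop augmentation, a registry of
    five VGG-family convolutional network variants implemented with
    compiled Armadillo kernels, a seeded training loop with binary
    cross-entropy loss, confusion-matrix based evaluation (accuracy,
    precision, recall, F1, rank-based AUC), a recursive image-quartering
    scan that locates the most informative spatial scale for phenotype
    classification, and an ablation harness over architectures,
    preprocessing and augmentation choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
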