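Package: histodbn
Title: Histopathology Image Classification with Fire-Module Features,
    Archimedes-Style Hyperparameter Search and Deep Belief Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary classification of
    histopathological breast-tissue images (benign vs malignant).  Images are
    denoised by median filtering and contrast enhanced (CLAHE or histogram
    equalization), mapped to fixed-length feature vectors by a compact
    fire-module (squeeze/expand) convolutional extractor, and classified by a
    stacked-RBM deep belief network pretrained with contrastive divergence,
    fine-tuned by an up-down (wake-sleep) pass, and trained with the Adamax
    infinity-norm update rule.  Extractor hyperparameters are tuned by a
    population metaheuristic with Archimedes-style density, volume and
    acceleration dynamics driven by a classifier error-rate objective.  A
    seeded generator of two-class histology-like texture images with realistic
    class imbalance, impulse noise and low contrast makes every stage testable
    without external data.  Evaluation follows stratified 80:20 and 70:30
    splits with per-class and averaged accuracy, sensitivity, specificity,
    F-score and Matthews correlation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
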