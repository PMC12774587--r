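Package: gpdeep
Title: Linear and Deep-Learning Genomic Prediction with Nonadditive
    Variance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, quality control, and analysis tools for comparing
    linear multi-component genomic prediction (GBLUP extended with dominance
    and additive-by-additive epistatic relationship matrices, fitted by
    average-information REML) against nonlinear deep-learning regressors
    (multilayer perceptrons and one-dimensional convolutional networks) on
    SNP genotype data.  Includes a phenotype-binned variational-autoencoder
    data augmentation scheme, a repeated train/validation split evaluation
    harness with splits-average and averaged-predictions (bagging-style)
    metrics, and a probe-matrix linearization method that extracts per-marker
    additive effects from any trained black-box predictor to estimate the
    nonadditive genetic variance it captures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
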