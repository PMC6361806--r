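Package: driverCNN
Title: Cancer Driver Gene Prediction from Somatic Mutations with
    Network-Structured Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cancer driver genes from tumor cohorts by combining
    twelve mutation-derived per-gene features (class fractions, ratiometric
    features and normalized mutation entropies) with a k-nearest-neighbor
    gene co-expression similarity network.  Each gene and its k most
    co-expressed neighbors are arranged into a 2k x 12 feature matrix that
    is classified by a small one-dimensional convolutional neural network.
    Includes MAF-style mutation parsing with hypermutation filtering,
    FPKM-to-TPM conversion and expression filtering, the downsampling and
    bagging cross-validation protocol for imbalanced driver/passenger
    labels, ROC/AUC evaluation, grid search, learning curves, ranking of
    unlabeled genes, and a seeded synthetic-cohort simulator for testing
    the full pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
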