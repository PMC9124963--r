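Package: tepsig
Title: Tumor-Educated Platelet RNA Diagnostic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cross-validated diagnostic gene signatures from
    tumor-educated platelet (TEP) RNA sequencing count data. Implements the
    full pipeline from a raw gene-by-sample count matrix to a validated
    support-vector-machine classifier: low-count gene filtering, discovery of
    library-size-tracking negative control genes, location-scale batch
    adjustment, removal of unwanted variation by factor analysis of control
    genes (RUVg-style), per-gene logistic-regression differential expression
    with Benjamini-Hochberg adjustment, minimum-redundancy-maximum-relevance
    (mRMR) feature ranking with a correlation-based mutual-information
    estimator, leave-one-out cross-validated Gaussian-kernel SVM training with
    grid search, Youden-index cutoff selection, and ROC/AUC evaluation with
    bootstrap confidence intervals. A negative-binomial simulator with known
    ground truth (control genes, planted effects, batch offsets, a latent
    technical factor) supports end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
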