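Package: eccdeconv
Title: Estimated Cell Composition Deconvolution of Bulk Leukemia
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the cellular composition of bulk acute myeloid
    leukemia (AML) RNA-seq samples by iteratively re-weighted non-negative
    least squares against a healthy bone-marrow single-cell reference,
    assigns each sample a maturation phenotype (its most abundant estimated
    cell type), and models downstream consequences of composition:
    ex-vivo drug resistance via leave-one-out random-forest regression,
    univariate/multivariate association ledgers with Benjamini-Hochberg
    correction, signature scoring, batch correction, and Kaplan-Meier /
    log-rank survival comparison. Includes synthetic single-cell atlas and
    pseudobulk simulators so the whole pipeline is testable end to end
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    randomForest,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    limma,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
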