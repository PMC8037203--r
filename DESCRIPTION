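Package: plasmiR
Title: Circulating miRNA Diagnostic Signatures from qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying circulating microRNA
    diagnostic classifiers from qPCR quantification-cycle (Cq) panels,
    covering hemolysis and detection-rate quality control, Livak
    2^-ddCt relative quantification with global-mean or
    endogenous-control references, quantile normalization, geNorm-style
    reference-gene stability ranking, random-variance-model moderated
    t-tests for marker screening, linear SVM recursive feature
    elimination with leave-one-out cross-validation, and diagnostic
    performance reporting with continuity-corrected Wilson confidence
    intervals and ROC/AUC. Includes a synthetic Cq data generator that
    emulates a TaqMan low-density-array cohort for end-to-end testing,
    and the published four-miRNA colorectal cancer score (let-7e-5p,
    miR-106a-5p, miR-28-3p, miR-542-5p) with scale-specific decision
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
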