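Package: pathreportr
Title: Curation of OCR'd Pathology Report Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for turning layout-aware OCR output of scanned
    pathology report PDFs into a labeled, machine-readable text corpus.
    It consumes Textract-dialect block JSON plus case metadata tables,
    applies patient-level case selection, whole-report screening for
    placeholder and discrepancy forms, structural and fuzzy-keyword
    detection of multiple-choice form pages, bounding-box excision of
    quality-control tables, handwriting and regex line cleaning, and
    text assembly with audit logging at every stage. A seeded synthetic
    document generator with planted, ground-truthed artifacts makes
    every stage testable without real data, and a one-vs-rest
    evaluation harness with a pluggable scorer benchmarks cancer-type
    classification on the assembled corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
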