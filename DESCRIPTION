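Package: polyAdiff
Title: Permutation Tests for Differential Poly(A) Site Usage and Tail
    Length in Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read-level statistical analyses for nanopore direct RNA
    sequencing summaries: per-gene permutation tests built on the
    1-Wasserstein (earth-mover) distance for differential poly(A)-site
    (3'-end) usage and for differential poly(A) tail-length
    distributions between two conditions, with Benjamini-Hochberg FDR
    control, a Fisher exact enrichment test for gene-category versus
    m6A-status contingency, and a synthetic cohort generator that
    emulates poly(A)-site mixtures, condition-dependent tail-length
    distributions with an optional ~30 nt periodic component,
    negative-binomial read depth, and a constant-tail spike-in
    calibration transcript.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
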