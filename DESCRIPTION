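Package: ibcrep
Title: Repertoire, Transcriptome and Insulin-Binding Kinetics of
    Insulin-Reactive B Cells
Version: 0.1.0
Authors@R: person("ibcrep", "maintainers", email = "ibcrep@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis pipeline for single-cell studies of
    insulin-reactive B cells in diabetes-prone mice: donor demultiplexing
    from hashtag-oligo counts, immunoglobulin kappa light-chain germline
    assignment and clonotype/CDR3 analysis with strain polymorphism and
    charge comparison, cluster marker detection with z-score projection
    onto a reference B-cell atlas, and insulin-binding quantification by
    ELISA titration AUC and 1:1 Langmuir SPR kinetic fitting.  A
    synthetic-data module reproduces the statistical structure of every
    input (contig tables, hashtag and expression count matrices,
    sensorgrams, ELISA titrations) together with ground-truth tables, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
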