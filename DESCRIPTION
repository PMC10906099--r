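Package: fatecourse
Title: Optimal-Transport Fate Inference for Single-Cell Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring cell-fate trajectories from multi-timepoint
    single-cell expression data. Implements quality control, size-factor
    normalisation, highly-variable-gene selection, PCA and mutual-nearest-
    neighbour batch correction; unbalanced entropic optimal transport between
    consecutive time points with iterative growth-rate learning; composition
    of couplings into fate (transition-probability) matrices toward terminal
    target populations; a log-odds fate-bias statistic with threshold-based
    landscape selection; maximum-mass descendant allocation; KNN reference-
    atlas label transfer; fate prediction for query cells with region-by-fate
    fraction tables and concordance scoring against observed fates; and
    cluster marker detection. Ships a lineage-tree timecourse simulator with
    analytic terminal-fate ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
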