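Package: chipcomposite
Title: Differential Expression and TSS-Anchored ChIP Composite Profiling
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A two-group differential-expression chain for array-style
    intensity matrices (variance-stabilizing transformation, robust spline
    normalization, empirical-Bayes moderated t-statistics with
    Benjamini-Hochberg false-discovery control, fold-change filtering, and
    hypergeometric gene-set over-representation) coupled to a ChIP-seq
    coverage profiler that computes depth-normalized, sliding-window,
    per-window-median composite profiles centred on transcription start
    sites, stratified by differential-expression call. Includes a
    synthetic-data generator with known ground truth (planted fold changes,
    heavy-tailed gene variances, Gaussian TSS chromatin peaks over Poisson
    background) so every stage is testable by parameter recovery, plus
    readers and writers for WIG, bedGraph, BED6, GFF3, TSV matrices and GMT
    gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
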