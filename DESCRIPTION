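Package: crosspath
Title: Cross-Dataset Pathway Expression and Guided Network Walk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for harmonized case/control differential expression across
    multiple microarray cohorts and for pathway-level downstream inference.
    Reads GEO Series Matrix expression tables, harmonizes them onto a common
    log2 scale via positive shift and quantile normalization, fits per-gene
    linear models with empirical-Bayes moderated t-statistics, and applies a
    probe-level filtering cascade (p-value cutoff, multi-sign probe removal,
    lowest-p deduplication, biotype/prefix exclusion). Downstream layers score
    pathways by over-representation and unweighted gene-set enrichment, compute
    pathway-level combined fold changes from member gene fold-change
    distributions, flag genes with consistent differential expression across
    datasets, run gene-guided random walks on pathway-to-pathway networks with
    an odds-ratio statistic against a topology-only null, and detect
    protein-protein interaction modules by edge-clustering-coefficient
    agglomeration. A synthetic-cohort generator with known ground truth makes
    every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
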