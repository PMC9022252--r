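Package: stagenet
Title: Stage-Resolved Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares stage-specific gene co-expression networks
    for staged disease cohorts (developed around colorectal cancer microarray
    data). Provides differential expression between neighboring stages with
    geometric-mean aggregation of probe p-values, Pearson correlation networks
    thresholded at an analytically derived critical correlation, Louvain
    community detection with a degree-preserving permutation test on
    normalized mutual information, edge-based hypergeometric gene-set
    enrichment, short-time-series trend profiling of stage medians for
    biomarker nomination, key-gene subnetwork extraction and drug-target-PPI
    network assembly, plus a synthetic-data generator with planted ground
    truth that makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
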