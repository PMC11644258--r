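Package: seedgrn
Title: Gene Regulatory Network Inference and Motif Analysis for Seed
    Development Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring and comparing gene regulatory networks
    from developmental time-course RNA-seq of seeds. Provides gene-set
    filtering (endosperm-enrichment classification, modified Shannon
    entropy filtering of time profiles, transcription-factor selection),
    two network inference engines (per-target random-forest importance
    ranking with iteration consensus and correlation-based sign
    assignment; kernel-PCA boosting with per-target posterior argmax
    edge selection), directed 3-node motif enrichment against
    degree-preserving randomized null networks with per-gene network
    motif scores, and permutation testing of edge overlap between
    inferred networks. Includes a synthetic-data generator with known
    ground truth so every stage can be benchmarked without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    kernlab,
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
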