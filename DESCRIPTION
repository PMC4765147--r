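Package: ipnet
Title: Metabolite-Weighted Co-Expression Networks and Candidate-Gene
    Screening for Seed Inositol Phosphate Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for nominating candidate genes in
    seed inositol phosphate (phytic acid) metabolism from expression and
    metabolite data. Provides germplasm screening of inbred-line pairs by
    the absolute log2 content-ratio (Q) statistic with an environment
    stability test; RPKM normalisation, gene filtering and differential
    expression calling under a fold-change and FDR gate; weighted gene
    co-expression network construction (Spearman correlation, soft
    thresholding, topological overlap, colour-named module detection,
    module eigengenes) with module-metabolite correlation screening;
    lossless power-graph compression of module networks; rule-based
    candidate-gene screening around guide genes (shared hubs, graph
    distance, power-node co-membership, domain and differential-expression
    preferences); plant-style miRNA target scoring; and seeded synthetic
    data generators with planted structure for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
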