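Package: qtnet
Title: Co-Expression Network Analysis of Genes Controlling Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the genes controlling a quantitative trait from
    transcript-level expression data: filters tabular homology-search hits
    into a gene-to-transcript catalog, tests trait genes for enrichment of
    alternative splicing against an organ-wide background, screens every
    transcript for correlation with the trait phenotype, builds hard-threshold
    co-expression networks with Markov clustering and vertex connectivity,
    quantifies the tendency of a trait-gene set to form a network against a
    bootstrap random-gene null across a p-value grid, and measures node and
    edge consistency of per-phenotype-group networks. Includes a seeded
    synthetic-data generator with ground-truth labels so the whole pipeline is
    testable without external transcriptome databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
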