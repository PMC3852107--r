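Package: lncarch
Title: Genomic Architecture and Expression Dynamics of lncRNA-Protein Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairs long non-coding RNA (lncRNA) genes with their nearest
    protein-coding neighbours and classifies each pair into one of 19 genomic
    architecture classes (antisense, intronic, intergenic, bidirectional
    promoter and promoter-associated super-classes). Calls differential
    expression from replicated 4-point timecourses using a Kendall-tau
    replicate-concordance rule with an endpoint fold-change cutoff, assigns
    temporal dynamic modes (rate and magnitude template families) by Pearson
    correlation, and quantifies architecture and mode frequency shifts across
    a nested filtration cascade with hypergeometric tests, fold enrichment
    and Bonferroni correction. Includes a synthetic-data generator that
    plants known architectures, modes and lncRNA-protein correlation signs
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
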