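Package: ripTargets
Title: miRNA Target Profiling from RISC Immunoprecipitation and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide microRNA target identification from paired
    RISC (AGO2) immunoprecipitation and gene-expression profiles.
    Combines RIP enrichment and expression repression ratios into a
    per-gene target score, scans transcripts for seed matches
    stratified by 5'UTR/CDS/3'UTR, and validates target sets with
    ranked-bin seed-frequency profiles and a 6-mer tiling scan along
    the guide. Includes a synthetic transcriptome and abundance
    simulator with planted targets so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
biocViews: GeneRegulation, GeneExpression, Sequencing, Transcriptomics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
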