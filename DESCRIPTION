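Package: mirqtl
Title: Haplotype-Based miRNA eQTL Mapping and Target-Hub Inference in
    Multiparental Mouse Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying microRNAs associated with allergic airway
    inflammation in an eight-founder multiparental mouse population. Implements
    founder-strain differential-expression screening with broad-sense
    heritability estimates (interclass correlation and coefficient of genetic
    determination), genome-wide haplotype-dosage regression eQTL scans with
    permutation-based significance thresholds, 1.5-LOD-drop support intervals,
    local/distal classification and conditional scans, candidate-region
    narrowing via founder allele-effect grouping and strain-distribution-pattern
    SNP filtering with a bootstrap neighbor-joining phylogeny, and a Monte
    Carlo miRNA target-hub enrichment analysis over phenotype-correlated
    transcripts. A synthetic-data generator reproduces the statistical
    structure of such studies so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ancestry.R'
    'eqtlScan.R'
    'founderExpression.R'
    'io.R'
    'networkHub.R'
    'simConfig.R'
    'simulate.R'
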