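Package: symbioseq
Title: Dual RNA-Seq Analysis of a Protist Host and Its Intracellular
    Bacterial Symbiont
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint transcriptomic analysis of a eukaryotic
    host and its intracellular bacterial symbiont from a single dual
    RNA-Seq experiment. Implements host differential-expression calling
    with a negative-binomial Wald test and median-of-ratios
    normalization, Gene Ontology enrichment at fixed hierarchy levels via
    one-sided Fisher tests with Benjamini-Hochberg correction, symbiont
    expression classification into active/inactive and percentile strata
    with COG and pangenome-partition enrichment, hypergeometric
    rarefaction for sequencing-depth assessment, core/soft-core
    refinement of pangenome partitions, Alien-Index screening for
    horizontal gene transfer from taxon-labelled homology hits, operon
    colocation analysis, and concatenated-supermatrix preparation. A
    seeded synthetic-data generator with planted ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer,
    vegan,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
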