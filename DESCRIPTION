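Package: embryoLnc
Title: lncRNA Identification, Temporal Specificity and Co-Expression
    Network Analysis for Pre-Implantation Embryo Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing long non-coding RNAs (lncRNAs) in
    stage-structured single-cell transcriptomes of pre-implantation
    embryos. Implements ROC-based selection of an optimal read-coverage
    threshold for assembled transcripts, a four-step novel-lncRNA
    detection pipeline (assembler intersection, annotation-overlap
    removal, size and exon-count filtering, coding-potential consensus),
    an entropy-based Jensen-Shannon temporal-specificity score with
    class-comparison statistics, cis neighbor-gene correlation analysis
    with a random coding-pair null, signed weighted co-expression network
    construction with topological overlap, module detection, eigengenes,
    module membership (kME) and hub extraction, and cross-species module
    preservation by hypergeometric overlap on an ortholog-mapped
    universe. Ships a synthetic-data generator that plants recoverable
    stage-specific genes, co-expression modules and neighbor pairs for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'lncfilter.R'
    'modules.R'
    'neighbors.R'
    'network.R'
    'preserve.R'
    'simulate.R'
    'specificity.R'
    'threshold.R'
    'utils.R'
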