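Package: TagDGE
Title: Digital Gene Expression 3' Tag Profiling: Simulation, Cleaning,
    Mapping, Differential Expression, Enrichment and Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested implementation of a SAGE-style digital gene
    expression tag profiling (DGEP) pipeline for single-replicate
    time-course libraries: raw 35-nt reads carrying a 3'-most NlaIII
    (CATG) anchored 17-nt tag are cleaned into tag libraries, mapped
    against a virtual CATG+17-nt tag database built from reference
    transcripts with at most one mismatch, summarised into a gene count
    matrix, normalised by the trimmed mean of M-values (TMM), tested for
    differential expression with the Audic-Claverie exact test under
    Benjamini-Hochberg control, profiled for GO and pathway enrichment
    with the hypergeometric/Fisher test, and partitioned into time-course
    expression patterns by K-means. A synthetic-data module generates
    reference transcriptomes, expression truth tables and raw tag reads
    with the statistical structure the pipeline assumes, so every stage
    is verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TagDGE-package.R'
    'utils.R'
    'cleaning.R'
    'clustering.R'
    'exact-test.R'
    'synthetic.R'
    'mapping.R'
    'normalize.R'
    'de.R'
    'enrichment.R'
    'io.R'
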