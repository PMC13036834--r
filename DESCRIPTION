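Package: trisomics
Title: Integrative Expression and Methylation Analysis for Trisomy 21
    Tissue Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired bulk RNA-seq and array-based DNA
    methylation studies of trisomy 21 (Down syndrome) tissue versus euploid
    controls. Implements marker-gene and projection-pursuit robust PCA
    sample quality control, negative-binomial Wald differential expression
    with chromosomal dosage-enrichment statistics, M-value differential
    methylation at position level and bump-hunting region level with a
    sample-permutation null, cis region-to-gene pairing, an integrative
    methylation-expression (eQTM) bootstrap/permutation analysis, and
    preranked gene-set enrichment with Jaccard clustering of significant
    sets. Includes a synthetic paired-study generator emulating the
    chromosome-21 dosage effect, planted differentially methylated regions
    and cis effects, and contaminated or deviant samples, so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
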