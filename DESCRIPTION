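Package: lincChIN
Title: Chromatin Interaction Network Analysis of LincRNA Regulatory Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcription-associated chromatin interaction networks
    (ChINs) from ChIA-PET interaction clusters and a GENCODE-style gene
    annotation, and characterizes long intergenic noncoding RNAs (lincRNAs)
    through them: interaction-category assignment (C1-C5), enhancer-like
    versus promoter-like promoter calling from H3K4me1/H3K4me3 coverage,
    ChromHMM state labelling of distal regulatory elements, permutation
    colocalization tests of genomic region sets, guilt-by-association
    function assignment via correlation-ranked gene set enrichment analysis,
    k-hop neighborhood RNA-target prediction against CHART/ChIRP binding
    peaks, cell-specificity scoring of expression profiles, and GWAS SNP to
    target-gene mapping through chromatin loops. Includes a seeded synthetic
    data generator that emulates every input with planted, recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
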