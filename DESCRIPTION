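Package: aseimprint
Title: Allele-Specific Expression and Imprinting Analysis for Hybrid Mouse RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing genomic imprinting from
    allele-specific RNA-seq of F1 hybrid (JF1 x C57BL/6) mouse cells.
    Covers SNP-table intersection and N-masking of a reference genome,
    SNP-based assignment of aligned reads to parental genomes, fragment
    counting per gene, median-of-ratios normalisation, allelic-ratio
    classification of imprinted expression, loss-of-imprinting calls
    between conditions, a simplified negative-binomial Wald test for
    differential expression, hypergeometric enrichment, and
    distance-to-binding-site statistics with a two-sample
    Kolmogorov-Smirnov comparison. A truth-tagged simulator of hybrid
    crosses (genomes, SNPs, paired-end alignments, negative-binomial
    counts, peak intervals) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    DESeq2,
    ggplot2
Config/testthat/edition: 3
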