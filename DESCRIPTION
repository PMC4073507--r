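Package: lincfinder
Title: Discovery and Characterisation of Long Intergenic Non-Coding RNAs
    from Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying long intergenic
    non-coding RNAs (lincRNAs) from assembled RNA-seq transcript models.
    Classifies transcripts against a reference annotation with
    Cuffcompare-style class codes, filters intergenic multi-exon candidates,
    and applies a three-stage coding-potential cascade: a codon-conservation
    score with empirical threshold calibration, a logistic coding-potential
    classifier over ORF, Fickett and hexamer-usage features with
    cross-validated cutoff selection, and a protein-motif filter on
    three-frame translations. Surviving lincRNAs are characterised by
    expression level, detection across samples, inter-individual coefficient
    of variation, SNP density in regulatory windows, all-pairs Spearman
    co-expression with Bonferroni control, and QTL-overlap enrichment.
    A synthetic-data module generates every pipeline input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
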