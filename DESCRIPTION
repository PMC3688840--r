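Package: geneclust
Title: Positional Clustering of Co-Localized, Co-Expressed and Co-Regulated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of gene co-localization, co-expression and
    co-regulation on annotated genomes. Provides configurable weighted genomic
    distance metrics (positional, promoter-anchored, centre-to-centre and
    intergenic gap distances, modulated by local gene density, expression
    similarity, shared transcription-factor repertoires or user plug-ins),
    three positional clustering algorithms (single-pass sequential threshold
    clustering, one-dimensional k-means with random, uniform and k-means++
    seeding, and max-gap clustering of orthology-bearing genes), and
    statistical significance procedures for the resulting clusters (random
    gene-set resampling with a one-sample t-test, an analytic neighbourhood
    null model for adjacent selected genes, Fisher's exact test for
    transcription-factor co-occurrence across clusters, and Mann-Whitney
    comparisons of expression between gene groups). Includes deterministic
    synthetic-fixture generators with planted cluster structure, file readers
    for common annotation dialects, and a scriptable pipeline entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
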