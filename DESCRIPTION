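Package: ribevol
Title: Cross-Species Translatome Analysis of Translational Efficiency
    Evolution
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to study the evolution of translational control from
    paired Ribo-seq and RNA-seq count data across species. Computes
    translational efficiency (TE) per gene and its between-species
    variance corrected for within-species sampling noise (TE_var), with
    permutation resampling and downsampling inference on gene groups;
    classifies species-specific regulatory modes (buffering, exclusive,
    intensified); assigns evolutionary ages to genes and small ORFs from
    coordinate-mapping and BLAST evidence and structural classes (intact,
    de novo, orphan) to young sORFs; computes the tau tissue-specificity
    index and Spearman co-regulation networks. A synthetic-data module
    generates negative-binomial count tables, toy multi-species genomes
    and tissue atlases with recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
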