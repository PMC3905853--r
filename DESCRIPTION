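Package: dretarget
Title: Predicting Target Genes of Distal Regulatory Elements from Hi-C and
    Phylogenetic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long-range relationships between distal regulatory
    elements (DREs, such as enhancers, repressors and insulators) and their
    target genes by combining Hi-C chromatin-contact read counts with the
    phylogenetic correlation of presence/absence profiles across a panel of
    vertebrate genomes. Includes DHS classification, genome-bin phylogenetic
    profiling, Hi-C pair counting with the intragenic-DHS maximum rule,
    replicate-repeatability cutoff grids, a cross-replicate rescue rule,
    single-linkage DRE clustering, Resnik GO semantic similarity and
    co-expression analyses with random-gene controls, marker-combination and
    differential-expression enrichment statistics, and a fully parameterised
    synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
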