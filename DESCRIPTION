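Package: ernascape
Title: Nascent Transcription, Enhancer RNAs, and Subgenome Expression Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific nascent transcription (GRO-seq
    and pNET-seq style 5'-end data) in large polyploid plant genomes. Builds
    normalized per-base polymerase position tracks, calls transcription start
    site clusters against a Poisson background, classifies intergenic
    transcription, derives transcribed and untranscribed enhancer-like elements
    from chromatin-state segmentations, assigns enhancers to target genes using
    histone-signal correlation and Hi-C contact support, and quantifies the
    association between subgenome-biased enhancer transcription and homoeolog
    expression dominance with odds ratios. Includes windowed nucleotide
    diversity, coverage-saturation curves, reporter-assay scoring, and a fully
    seeded synthetic hexaploid genome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    withr,
    ggplot2,
    jsonlite,
    generics,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
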