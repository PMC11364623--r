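Package: ervcre
Title: Cryptic ERV-Derived Enhancers and Bivalent Promoter Chromatin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative downstream analysis of histone-mark ChIP-seq, nascent
    transcription and expression data for chromatin-perturbation experiments in
    embryonic stem cells. Provides consensus peak and interval arithmetic on
    GenomicRanges, RPGC and spike-in track normalization, region signal
    matrices and metaprofiles, a self-contained moderated-t/permutation
    differential engine with Benjamini-Hochberg adjustment, k-means clustering
    of differentially abundant heterochromatin regions, bivalent promoter
    calling, Polycomb H3K27me3 spreading analysis around SUZ12 peaks,
    shuffle-based transposable-element enrichment with empirical p-values,
    enhancer strength stratification, a distance-and-correlation enhancer-gene
    linker, and a seeded synthetic-data generator that emulates the full study
    design with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
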