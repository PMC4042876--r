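Package: ctdseq
Title: Occupancy Analysis of RNA Polymerase II CTD Phospho-Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for binned ChIP-seq, MNase-seq and
    strand-specific short-RNA coverage tracks, focused on the promoter and
    enhancer occupancy of RNA polymerase II carboxy-terminal-domain (CTD)
    phospho-isoforms (Tyr1P, Ser2P, Ser5P, Ser7P). Provides tag
    pre-processing (pile filtering, in-silico fragment-length estimation,
    elongation, binning, input subtraction, nucleosome density and dyad
    midpoint modes), selection of significantly bound genes by
    two-component Gaussian mixture thresholds, anchored and composite
    metagene profiling, antisense/sense paused-transcription statistics,
    promoter classification by the position of the dominant upstream peak,
    spatial organisation of isoform maxima relative to Pol II, peak calling
    and two enhancer/promoter classification workflows (Pol II-based and
    H3K27ac-based) with H3K4me3/me1 ratio thresholding and
    tissue-specificity ranking. A synthetic-genome generator plants every
    structure the downstream analyses assume, so the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
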