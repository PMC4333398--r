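Package: nascentr
Title: Analysis of Genomic Run-On Nascent Transcription Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific, probe-level nascent
    transcription (genomic run-on) signal together with total-polymerase
    ChIP, mature mRNA and genomic-DNA control tracks. Provides
    normalization against a genomic-DNA control, correction of the
    run-on 5' displacement, anchor-aligned metagene matrices and average
    profiles, nucleosome-phasing statistics (autocorrelation period,
    peak calling, cross-condition displacement, nascent-vs-mature
    boundary extensions), k-means clustering of chromatin and
    occupancy profiles, and per-gene nascent transcription rate (nTR)
    quantification with gene-class and tRNA-family aggregation. A
    synthetic-data generator emulates the statistical structure of
    tiling-array run-on experiments (probe grids, nucleosome-phased
    active fraction, run-on displacement, ChIP smearing, polymerase
    class contrasts and condition variants) so that every stage of the
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    zoo,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
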