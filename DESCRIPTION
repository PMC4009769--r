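Package: tescout
Title: Population-Scale Calling of Transposable Element Insertions from
    Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Calls novel and reference occurrences of annotated transposable
    elements (TEs) from paired-end sequencing alignments.  Read pairs with one
    end anchored uniquely outside all annotated TEs and the mate inside a TE
    are collected, clustered at a chosen level of the TE hierarchy (element,
    family, superfamily or class), and merged across a population so that
    low-coverage individuals benefit from events shared with well-covered
    ones.  The package also ships a paired-read simulator built around a
    "virtual reference" (TE-free chromosomes plus one contig per annotated
    element) with a truth-alignment emitter for aligner-free validation,
    false-positive/false-negative benchmarking of calls against planted
    insertions, and windowed pairwise-difference diversity statistics on
    event presence/absence matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
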