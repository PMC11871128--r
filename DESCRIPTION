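Package: l1rt
Title: Somatic LINE-1 Retrotransposition Calling and Multi-Omic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic LINE-1 (L1) retrotransposition from paired
    tumor/normal short-read alignments using clipped-read and discordant-pair
    evidence, realigns clipped tails to the L1 consensus to infer insertion
    length, twin-priming inversions, target-site duplications and 3'
    transductions, and classifies calls as somatic or pseudo-germline.
    Includes a mechanistically faithful insertion/read simulator with an
    oracle aligner, a synthetic multi-omic cohort generator, QC residual
    adjustment of RNA/RT estimates, locus-efficiency regression models with
    permutation backgrounds, and a p53 dual-regulation mediation analysis
    with bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
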