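Package: seedmapr
Title: Seed-Hash Short-Read Mapping with Pile-Up Variant Calling and RPKM
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-hash short-read mapper: a whole-reference exact k-mer
    index, hotspot generation that tolerates short indels by banding seed
    diagonals, prioritized end-to-end dynamic-programming verification,
    and unique/multi/unmapped classification with export of all best
    mapping locations. Downstream tools build per-site pile-ups from
    uniquely mapped reads, call SNVs and short indels with a Fisher's
    exact test against a sequencing error model, and quantify transcript
    abundance in RPKM. A read simulator with ground-truth tracking and an
    evaluation harness measure sensitivity and mismapping rate on
    synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
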