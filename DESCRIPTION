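Package: cenarch
Title: Centromere Repeat Archaeology from Assembled Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the recent history of centromeric repeat
    regions from assembled sequence. Dates long terminal repeat (LTR)
    retrotransposon insertions and segmental duplications with a Kimura
    two-parameter molecular clock, pairs LTRs by target site duplication and
    terminal-edge filters, detects and dates higher-order repeats (HORs) in
    tandem satellite arrays via reciprocal-nearest-neighbour monomer pairing
    on the pairwise distance structure, localizes deletion and duplication
    breakpoints and measures the microhomology that mediated them, computes
    windowed smoothed ChIP/input enrichment profiles, quantifies assembly
    discrepancy rates in overlap regions, and ships a seeded synthetic-data
    generator so every estimator is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    rtracklayer,
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
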