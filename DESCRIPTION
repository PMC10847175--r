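Package: intragenic
Title: Intragenic T-DNA Border Discovery, Construct Assembly and
    Integration-Site Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intragenic plant transformation analysis: discovery of
    host-derived T-DNA border-like sequences with a degenerate 24-bp consensus
    motif, in-silico restriction-ligation assembly of intragenic binary
    vectors with per-fragment provenance and in-silico PCR, vector-anchored
    paired-end detection of T-DNA insertion sites with a vector-backbone
    screen, base-resolution characterization of integration junctions (border
    transfer, truncation, target-site deletion, microhomology), chi-square
    tests of Mendelian segregation of the selectable marker, and a
    deterministic simulator that generates genomes, constructs, integration
    events, read pairs and progeny counts with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
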