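Package: tasitune
Title: Design and Efficacy Tuning of Synthetic Trans-Acting siRNA Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing plant synthetic trans-acting small
    interfering RNA (syn-tasiRNA) constructs with tunable silencing
    efficacy. Designs 21-nt guide RNAs against a target transcript,
    screens them against a transcriptome with a TargetFinder-style
    penalty scheme, generates consecutive 3'-end mismatch variant
    series, places guides into DCL4 processing positions 3'D2[+] to
    3'D5[+] of an AtTAS1c-based precursor, emits BsaI golden-gate
    cloning oligonucleotides with TTTA/CCGA overhangs, simulates
    digestion, ligation and phased 21-nt processing, and predicts an
    ordinal silencing-efficacy tier from the combination of precursor
    position and guide/target 3'-end complementarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
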