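Package: mlstpop
Title: Population Genetics of Clonal Bacteria from MLST Profiles and PFGE Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus sequence typing (MLST) based population
    genetics of essentially clonal bacteria such as Lactococcus lactis.
    Covers allele numbering and sequence-type (ST) assignment, nucleotide
    diversity statistics (pi, pi_MAX and their ratio as a sampling
    diagnostic), Tajima's D and Fu & Li's outgroup D and F neutrality
    tests with coalescent Monte-Carlo significance, the standardized
    index of association (clonality test), eBURST-style clonal-complex
    and founder inference with per-site recombination-to-mutation (r/m)
    classification, Kimura two-parameter neighbor-joining trees with
    bootstrap, pulsed-field gel electrophoresis (PFGE) fingerprint
    comparison (Dice/UPGMA) and genome-size estimation, typing-scheme
    locus-subset optimisation, and a synthetic clonal-population
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
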