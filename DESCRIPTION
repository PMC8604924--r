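Package: rtqtl
Title: Genetic Mapping of DNA Replication Timing Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers DNA replication-timing profiles from windowed read-depth
    (copy-number) data in proliferating cell populations, calls replication
    initiation peaks and inter-individual timing-variant regions, maps
    cis-acting replication-timing quantitative trait loci (rtQTLs) with a
    two-step permutation scheme and empirical per-window FDR thresholds,
    characterises multi-rtQTL regions and additive versus synergistic allele
    architecture, performs matched-control permutation enrichment of
    epigenetic features at rtQTLs including an iterative histone-mark
    combination search, and evaluates interval-based prediction of
    replication initiation sites. Ships a synthetic-cohort generator with a
    planted-truth table so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
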