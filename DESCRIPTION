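Package: topokaryo
Title: Quantitative Analysis of Nuclear Envelope Association Patterns on
    Mitotic Chromosomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for topokaryotyping data: reconstructs per-domain
    nuclear-envelope association frequencies from single-cell chromosome
    banding patterns, tests the independence model of domain association
    against observed pattern spectra, discriminates cooperative, stochastic
    and mutually exclusive association modes by maximum likelihood and AIC,
    and computes binned log2 IP/input enrichment tracks with adjacent-bin
    smoothing and Monte Carlo testing of signal at lamina-associated
    domains.  Synthetic-data generators emulate both data modalities (per
    mitotic-spread domain annotations under explicit association models,
    and IP/input fragment sets over a toy genome with planted enrichment)
    so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
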