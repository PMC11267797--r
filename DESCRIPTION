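Package: sabr
Title: Building-Block- and Reaction-Aware Synthetic Accessibility Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how easy a small molecule is to synthesize by scoring
    its atom-centred circular fragments (ECFP4-style environments) against two
    knowledge corpora: fragments present in purchasable building blocks and
    fragments formed at the reaction centres of recorded, atom-mapped
    reactions. Fragment scores are combined with a four-term structural
    complexity penalty (size, stereocentres, bridgehead/spiro ring atoms,
    macrocycles) and normalized to the familiar 1 (easy) to 10 (hard)
    synthetic-accessibility scale, with per-atom score attributions for
    interpretability. Includes a deterministic synthetic fixture generator,
    precision-recall and ROC evaluation utilities, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
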