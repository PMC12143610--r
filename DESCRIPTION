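Package: cytofoci
Title: Cytoplasmic dsDNA Focus Quantification and Radiation Response Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cytoplasmic double-stranded DNA (dsDNA) foci from
    three-channel fluorescence microscopy fields (dsDNA immunostain, DAPI
    nucleus stain, phalloidin cytoplasm stain) using compartment-restricted
    spot calling, and carries the counts through the downstream analytics of
    a radiation-quality comparison study: linear dose-response fits with
    slope comparison, exponential-saturation (plateau) fits, linear-quadratic
    clonogenic survival with relative biological effectiveness (RBE) at a
    chosen survival level, 2^(-ddCt) relative qPCR quantification, fold
    change/p/FPKM differential-expression filtering, and per-gene Z-score
    summaries. A seeded synthetic-data module generates ground-truthed
    fields, colony counts, Cq tables and FPKM matrices so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
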