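Package: hotspotr
Title: Predicting Disease-Variant Hotspot Residues from Residue Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein residue contact networks from predicted
    contact-probability matrices or 3-D coordinates, computes twenty
    per-residue node-importance scores (weighted-degree family, classical
    network centralities, and sequence-based Gaussian network model
    dynamics), and combines them with tree-ensemble classifiers to
    discriminate deleterious from neutral variant sites. Includes a
    synthetic-cohort generator with a known core-connectivity label signal
    for end-to-end validation, broom-style tidiers, ggplot2 plotting
    methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    optparse,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
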