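Package: oetomics
Title: Protein, Translatome and Transcriptome Dynamics Across the Mouse
    Oocyte-to-Embryo Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of stage-resolved proteome (log2 iBAQ),
    translatome (ribosome-protected fragment FPKM) and transcriptome (mRNA
    FPKM) matrices spanning the mouse oocyte-to-embryo transition (FGO to
    blastocyst). Provides FGO-anchored batch correction and replicate
    merging for label-free proteomics, coefficient-of-variation dynamics
    classification, trajectory clustering, gene-wise and lagged
    protein-translation concordance, differential-abundance calling with
    attribution of protein changes to transcriptional or translational
    regulation, allele-specific protein expression analysis, and a
    mass-action kinetic model that predicts protein trajectories from
    translation profiles plus the initial oocyte protein stock. A
    synthetic-data generator with known per-gene kinetic parameters, batch
    offsets and detection dropout makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
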