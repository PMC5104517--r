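Package: straincycle
Title: Cell-Cycle Quantification in Strained Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify cell-cycle progression in quiescent epithelial
    monolayers subjected to equi-biaxial mechanical strain, from Fucci
    (mKO2-Cdt1 / mAG-Geminin) time-lapse imaging. Provides an agent-based
    monolayer simulator with a two-threshold beta-catenin activity model and a
    synthetic image renderer for ground-truthed testing; nuclear segmentation
    and per-nucleus intensity quantification; single-cell tracking with gap
    closing and division detection; Fucci trace classification and cell-cycle
    event counting; strain estimation from fiducial bead displacements and
    from the 7-nearest-neighbour distance metric; and the statistical layer
    (Welch t-tests with Holm-Sidak step-down correction, two-sample
    Kolmogorov-Smirnov tests, mean +/- SEM summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
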