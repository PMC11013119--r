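Package: monodomain
Title: Nanoscale Domain Analysis of Lipid Monolayer AFM/KPFM Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phase-separated lipid and lipid-gemini-surfactant
    monolayers imaged by atomic force microscopy (AFM, topography) and Kelvin
    probe force microscopy (KPFM, electrical surface potential). Provides a
    ground-truthed synthetic image generator for two-phase films, plane and
    scan-line levelling, two surface-coverage estimators (bimodal-histogram
    threshold and particle detection) with a combined model average,
    cross-section step statistics for domain height and potential contrasts
    with 95% confidence margins, and monolayer electrostatics (Helmholtz
    dipole-sheet and charged-sheet models) including a curated literature
    table for DOPC and DPPC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
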