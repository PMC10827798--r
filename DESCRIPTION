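Package: ChoroidStrat
Title: Choroidal Sublayer Stratification and Binarization of EDI-OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stratifies the choroid of enhanced depth imaging optical
    coherence tomography (EDI-OCT) B-scans into choriocapillaris, Sattler's
    and Haller's layers and quantifies their luminal and stromal composition.
    Implements lumen-referenced brightness calibration, 256-gradation
    conversion and binarization of a 1500-um foveal region of interest;
    sublayer boundary detection from depth brightness profiles by
    second-order differentiation with quadratic boundary fitting; per-layer
    choroidal, luminal and stromal areas, luminal/choroidal (L/C) ratios and
    central thicknesses; and the accompanying statistical battery
    (intraclass correlation, Bland-Altman agreement, Spearman correlation,
    standardized multiple regression on ocular covariates, Kruskal-Wallis).
    Ships a synthetic B-scan phantom and cohort generator with exact ground
    truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
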