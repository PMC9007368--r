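Package: etdrsmag
Title: Transverse Magnification Correction for ETDRS Macular Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of Early Treatment of Diabetic Retinopathy Study
    (ETDRS) macular thickness profiles from segmented spectral-domain OCT
    raster scans, with and without correction of the transverse scale for the
    eye's axial length relative to the scanner's assumed axial length.
    Includes a synthetic foveal-pit cohort generator that reproduces the
    magnification mechanism of a raster scanner, per-sector thickness
    averaging on the 9-region ETDRS grid, and linear mixed models for the
    cohort-level comparison of raw versus corrected thickness in paired eyes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    pracma,
    ggplot2,
    rlang,
    yaml,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
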