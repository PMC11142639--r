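Package: gocquant
Title: Quantification of Transzonal Projections in Granulosa Cell-Oocyte Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification and statistical toolkit for measuring
    transzonal projections (TZPs), the filopodia-like processes that connect
    granulosa cells to the growing oocyte across the zona pellucida.
    Implements equatorial TZP counting by circular intensity-profile peak
    detection with diameter normalization, 3D morphometrics (membrane-based
    cell segmentation with a volume filter, volume/surface-area/sphericity,
    filament length and width, filament-to-spots discretization, signed
    distance to the oocyte surface and the toward/away orientation
    statistic), FRAP-based gap-junctional coupling analysis, EdU labelling
    fractions, 2^-ddCt relative expression, and the study-style group
    summaries and t-tests.  A synthetic ground-truth generator produces
    equatorial images, 3D volumes, filament sets, FRAP traces and two-group
    experiments with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    tiff,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
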