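Package: rootplates
Title: Quantify Cereal Seedling Root Growth from Soil-Plate Tracing Exports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification layer for soil-plate seedling root phenotyping
    experiments in cereals. Reads CSV exports of traced roots and shoots
    (SmartRoot-style structure labels), recovers millimetre lengths from
    polyline tracings via an in-image 16 mm reference strip, compiles
    well-watered versus PEG water-stressed time courses (days 0-2) with
    explicit measured/occluded/absent replicate accounting for late-emerging
    seminal roots, tests per-structure per-timepoint treatment contrasts with
    linear mixed models, and renders root plots and difference plots. Includes
    a seeded simulator of the full plate experiment so the pipeline is
    testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    emmeans,
    ggplot2,
    patchwork,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
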