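Package: agingV1
Title: Age-Related Decline of Neuronal Function and GABAergic Markers in Rat
    Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the analysis of age-related
    functional decline in rat primary visual cortex (V1). Covers single-unit
    tuning-curve analysis (double-Gaussian direction tuning fits with a
    fitting-error filter, orientation and direction selectivity indices,
    optimal and average responses, spontaneous activity, signal-to-noise
    ratio, and F1/F0 simple/complex classification), group-level statistics
    (binned distributions with chi-square tests, t-tests, balanced two-way
    ANOVA, percent-change summaries), and quantification of GABAergic markers
    in double-labelled sections (cell segmentation, double-label matching,
    per-layer density and proportion tables, fluorescence intensity, western
    blot densitometry normalized to GAPDH). A seeded synthetic-data generator
    emulates the study's recordings and histology so every stage runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
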