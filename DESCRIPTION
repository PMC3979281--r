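Package: swerf
Title: Size-Weighted Relevant Fine Fraction of Bulk Powders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the size-weighted relevant fine (respirable-equivalent)
    fraction (SWeRF) of a bulk powder, and of its crystalline-silica
    constituent, either by weighting a measured particle size distribution
    with the EN 481 respirable sampling convention or by evaluating
    gravimetric sedimentation experiments whose cut-off is matched to the
    convention through Stokes' law. Derives the GHS/CLP STOT RE hazard
    classification from the fine-fraction crystalline silica content, and
    ships a synthetic-data generator for lognormal powders, spiked mineral
    blends and noisy virtual sedimentation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
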