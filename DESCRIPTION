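Package: sinkassay
Title: Phytoplankton Sinking Rates from Plate-Fluorometer Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts top-view chlorophyll-a fluorescence time series from
    microtitre well plates into phytoplankton sinking rates (m per day).
    Implements min-max scaling of relative fluorescence, an inverse-square
    emission-decay model, square-root linearization, single-line and
    one-breakpoint segmented regression with correction for the transient
    fluorescence rise caused by non-photochemical quenching relaxation,
    amplitude partitioning between sinking subpopulations, Gompertz
    growth-curve fitting for staging cultures, and a seeded synthetic trace
    simulator for validating every pipeline stage without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
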