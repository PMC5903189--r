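Package: stemcarbon
Title: Forest Stem Carbon Stocks from Nested-Plot Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating forest stem carbon stocks from nested
    concentric-plot inventories and for analysing the factors associated with
    them. Implements the arithmetic of a two-phase systematic cluster sampling
    design, per-hectare expansion of nested circular plots, log-linear
    allometric stem volume, wood-density biomass and carbon conversion,
    height-diameter curve fitting, a sum-contrast multiple linear regression of
    subplot carbon on categorized stand and site factors with
    confidence-interval classification of factor levels against the overall
    mean, a residual-threshold outlier removal-and-refit pass, and a calibrated
    synthetic inventory generator so the whole chain is testable without field
    data.
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
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
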