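Package: ipdrates
Title: Gross Nitrogen Transformation Rates from 15N Isotope Pool Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of 15N isotope pool dilution (IPD) assays for gross
    nitrogen mineralization and nitrification in soils, waste and other
    solid matrices. Implements blank correction of measured 15N atom
    percentages, atom-percent-excess accounting against natural-abundance
    backgrounds, the Kirkham-Bartholomew two-pool rate equations for gross
    production and consumption, validity screening (exclusion of pairs
    whose enrichment fails to decline), tracer planning for pool and spike
    amendments, headspace N2O enrichment screening, and group-level
    summaries with one-way ANOVA and Tukey HSD comparisons. A forward
    simulator of the constant-rate pool-dilution process provides
    ground-truth data for validating every stage of the pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
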