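Package: wetcarbon
Title: Design-Based Wetland Soil Carbon Stock Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computing wetland soil organic carbon stocks from
    horizon-described soil profiles and probability-survey site data, in the
    style of the National Wetland Condition Assessment (NWCA). Provides
    horizon-level carbon density computation with 1-cm depth slicing and
    arbitrary depth-range aggregation, quality-control rules for missing
    carbon and suspect bulk density, gradient-boosted-tree bulk density
    imputation, rule-based organic/mineral (histosol-derived) soil
    classification, stressor-threshold disturbance screening, and
    design-based (Horvitz-Thompson) estimation of subpopulation means and
    totals with inference-to-target population scaling. Includes a synthetic
    survey generator with known ground truth so every stage of the pipeline
    is testable without access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
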