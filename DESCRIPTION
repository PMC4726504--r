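Package: nutrisupply
Title: Nutrient Supply Estimation from Food Balance Sheet Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for converting commodity-balance style food data
    into per-capita edible food supplies and national dietary nutrient
    supplies. Broad commodity categories are disaggregated into individual
    foods by replicating the balance-sheet method on production and trade
    data; residual "not elsewhere specified" fruit and vegetable amounts
    are resolved via data-quality flags and redistribution rules; primary
    weights are converted to edible weights via carcass-to-retail and
    discard factors; refined flours and milk-equivalent cheeses are
    handled explicitly. Nutrient supplies for 23 tracked nutrients are
    estimated with a Monte Carlo simulation over candidate food
    composition entries, yielding medians and 95% uncertainty intervals,
    with optional fortification overlays and disaggregation into age-sex
    demographic groups via intake ratios and energy-requirement
    proportional calorie allocation. A seeded synthetic fixture generator
    emulates every input table so the full pipeline can run and be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
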