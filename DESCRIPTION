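Package: fbdgcarbon
Title: Carbon Footprint Modelling of Food-Based Dietary Guidelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the cradle-to-farm-gate greenhouse-gas footprint of national
    food-based dietary guidelines (FBDG). Normalizes heterogeneous guideline
    recommendations (grams, ounces, cups, pieces, millilitres) to a common
    2000-kcal mass basis, derives within-group apparent-consumption proportions
    from food-balance-sheet-style supply tables via edible/cooked-weight
    conversion chains, and computes per-group and total diet emissions as
    consumption-weighted averages of per-kilogram emission intensities.
    Includes a counterfactual comparison that evaluates every guideline under a
    single reference consumption pattern, a synthetic-data generator for fully
    reproducible end-to-end testing, and config-driven batch reporting.
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
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
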