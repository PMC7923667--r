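#' Path to a packaged example data file
#'
#' @param ... Path components under the package's `extdata` directory.
#' @return Absolute path to the installed file.
#' @export
fbdg_example_path <- function(...) {
  path <- system.file("extdata", ..., package = "fbdgcarbon", mustWork = TRUE)
  path
}

#' The US fruit worked example
#'
#' A fully worked single-group calculation packaged as a fixture: the US
#' fruit recommendation of 2 cups/day, the ten balance-sheet fruit
#' commodities with their published apparent-consumption proportions,
#' cup-to-kg conversion factors, and per-kg emission intensities, plus the
#' published per-commodity contributions for regression checks.
#'
#' The published proportions sum to 1.001 (they were rounded to 3 decimals at
#' source), so the pattern is constructed with a matching share-sum tolerance
#' and deliberately not renormalized: feeding the printed numbers straight
#' through [group_footprint()] reproduces the published 0.165 kg CO2-eq/day.
#'
#' @return A list with `rec_amount` (2), `unit` (`"cup"`), `pattern`
#'   ([consumption_pattern()]), `conversions` (cup-to-kg, cooked-to-raw = 1),
#'   `impacts` ([impact_factor_table()]), `printed` (the source rows,
#'   including the published `ghge_printed` column), and `total_printed`
#'   (0.165).
#' @export
us_fruit_example <- function() {
  printed <- readr::read_csv(
    fbdg_example_path("us_fruit_example.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  pattern <- consumption_pattern(
    country = "United States", group = "fruit",
    shares = setNames(printed$proportion, printed$commodity),
    tol = 5e-3
  )
  conversions <- tibble(
    commodity = printed$commodity,
    cup_to_kg = printed$cup_to_kg,
    cooked_to_raw = 1
  )
  impacts <- impact_factor_table(
    tibble(commodity = printed$commodity,
           kg_co2e_per_kg = printed$kg_co2e_per_kg)
  )
  list(
    rec_amount = 2, unit = "cup",
    pattern = pattern, conversions = conversions, impacts = impacts,
    printed = printed, total_printed = 0.165
  )
}

#' Published reference results for the packaged guideline examples
#'
#' Per-group and total footprints (kg CO2-eq/day, 2000-kcal basis) as
#' previously reported for the nine packaged guideline sets, under each
#' country's own consumption pattern (`"baseline"`) and under the common US
#' reference pattern with its ratio column (`"controlled"`). Cells carry the
#' source's display rounding (2 decimals); they are used for
#' arithmetic-identity regression tests, not recomputed from raw data, since
#' the underlying supply and intensity databases are not redistributed here.
#'
#' @param type `"baseline"` or `"controlled"`.
#' @return A tibble, one row per guideline set.
#' @export
reference_results <- function(type = c("baseline", "controlled")) {
  type <- match.arg(type)
  readr::read_csv(
    fbdg_example_path("reference", paste0(type, "_reference.csv")),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Load the packaged guideline configs
#'
#' Nine guideline sets (seven national FBDG, the US vegetarian adaptation,
#' and the EAT-Lancet reference diet), transcribed on a common 2000-kcal
#' basis.
#'
#' @return A named list of [guideline_set()] objects, keyed by country label.
#' @export
example_guidelines <- function() {
  dir <- fbdg_example_path("guidelines")
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  sets <- lapply(files, read_guideline)
  setNames(sets, map_chr(sets, function(g) g$country))
}
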