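#' Construct or validate an impact-factor table
#'
#' Emission intensities are mean cradle-to-farm-gate greenhouse-gas emissions
#' per kilogram of raw edible food (kg CO2-eq/kg), compiled from life-cycle
#' assessments. A commodity absent from the table is an explicit absent state
#' — lookups fail loudly, never silently return zero — so that exclusions are
#' auditable upstream (see `excluded_share` in [compute_pattern()]).
#'
#' @param impacts A data frame with columns `commodity`, `kg_co2e_per_kg`,
#'   and optionally `source_note`.
#' @return A validated tibble.
#' @export
impact_factor_table <- function(impacts) {
  impacts <- as_tibble(impacts)
  required <- c("commodity", "kg_co2e_per_kg")
  missing_cols <- setdiff(required, names(impacts))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "Impact table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(is.na(impacts$kg_co2e_per_kg) | impacts$kg_co2e_per_kg < 0)) {
    stop_validation("Emission intensities must be nonnegative.")
  }
  if (anyDuplicated(impacts$commodity)) {
    stop_validation("Impact table has duplicated commodities.")
  }
  if (!"source_note" %in% names(impacts)) {
    impacts$source_note <- NA_character_
  }
  impacts
}

#' Read an impact-factor table from CSV
#'
#' @param path Path to a CSV with columns `commodity`, `kg_co2e_per_kg`,
#'   and optionally `source_note`.
#' @return A validated tibble (see [impact_factor_table()]).
#' @export
read_impact_table <- function(path) {
  impact_factor_table(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' Does the impact table cover these commodities?
#'
#' @param impacts Impact-factor table.
#' @param commodity Character vector of commodity labels.
#' @return Logical vector.
#' @export
has_impact <- function(impacts, commodity) {
  commodity %in% impacts$commodity
}

#' Look up an emission intensity
#'
#' @param impacts Impact-factor table.
#' @param commodity Single commodity label.
#' @return Intensity in kg CO2-eq per kg raw edible food.
#' @export
impact_intensity <- function(impacts, commodity) {
  i <- match(commodity, impacts$commodity)
  if (is.na(i)) {
    stop_missing_reference(
      sprintf("No emission intensity for commodity '%s'.", commodity),
      commodity = commodity
    )
  }
  impacts$kg_co2e_per_kg[i]
}
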