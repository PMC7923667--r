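#' Convert a volume measure to grams by calorie equivalence
#'
#' Guidelines that express recommendations by volume (cups) are converted to a
#' mass basis by equating energy: a cup of a food weighs
#' `100 * kcal_per_cup / kcal_per_100g` grams. The classic worked example is
#' black beans: a cup has 662 kcal and 100 g has 341 kcal, so one cup is
#' equivalent to 194 g.
#'
#' Full precision is kept internally; round only for display.
#'
#' @param kcal_per_cup Energy content of one cup (kcal), positive.
#' @param kcal_per_100g Energy content of 100 g (kcal), positive.
#' @return Mass in grams per cup. Vectorised over both arguments.
#' @examples
#' cup_to_grams(662, 341) # ~194 g per cup of black beans
#' @export
cup_to_grams <- function(kcal_per_cup, kcal_per_100g) {
  if (!is.numeric(kcal_per_cup) || !is.numeric(kcal_per_100g) ||
      anyNA(kcal_per_cup) || anyNA(kcal_per_100g) ||
      any(kcal_per_cup <= 0) || any(kcal_per_100g <= 0)) {
    stop_validation("`kcal_per_cup` and `kcal_per_100g` must be positive numbers.")
  }
  100 * kcal_per_cup / kcal_per_100g
}

#' Average conversion factor for an aggregate commodity
#'
#' Balance-sheet commodities such as "nuts and products" or "freshwater fish"
#' aggregate several foods; their conversion factor is the unweighted
#' arithmetic mean of the member foods' factors.
#'
#' @param member_factors Numeric vector of positive per-food factors.
#' @return A single averaged factor.
#' @export
aggregate_conversion <- function(member_factors) {
  if (length(member_factors) == 0L) {
    stop_validation("`member_factors` must be a nonempty vector of factors.")
  }
  if (!is.numeric(member_factors) || anyNA(member_factors) ||
      any(member_factors <= 0)) {
    stop_validation("`member_factors` must all be positive numbers.")
  }
  mean(member_factors)
}

#' Convert a cooked mass to its raw edible equivalent
#'
#' Recommendations are stated in cooked weights while emission intensities are
#' per kilogram of raw edible food; the factor is raw kg per cooked kg
#' (above 1 for foods that lose water in cooking, below 1 for grains and
#' legumes that take up water).
#'
#' @param mass_cooked Cooked mass (any mass unit).
#' @param factor Raw-per-cooked conversion factor, positive.
#' @return Raw edible mass in the same unit as `mass_cooked`.
#' @export
cooked_to_raw <- function(mass_cooked, factor) {
  if (!is.numeric(factor) || anyNA(factor) || any(factor <= 0)) {
    stop_validation("`factor` must be positive.")
  }
  if (!is.numeric(mass_cooked) || anyNA(mass_cooked) || any(mass_cooked < 0)) {
    stop_validation("`mass_cooked` must be nonnegative.")
  }
  mass_cooked * factor
}

#' Convert a milk volume to mass
#'
#' Dairy recommendations are expressed as volumes; milk's density of
#' 1.0305 g/ml converts them to mass. Other dairy products default to the same
#' density unless one is supplied.
#'
#' @param volume Volume in ml, nonnegative.
#' @param density Density in g/ml (default 1.0305, whole milk).
#' @return Mass in grams.
#' @export
milk_volume_to_mass <- function(volume, density = MILK_DENSITY_G_PER_ML) {
  if (!is.numeric(volume) || anyNA(volume) || any(volume < 0)) {
    stop_validation("`volume` must be nonnegative.")
  }
  check_number(density, "density", min = 0, strict = TRUE)
  volume * density
}

#' Convert ounces to grams
#'
#' @param oz Mass in ounces, nonnegative.
#' @return Mass in grams (28.3495 g/oz).
#' @export
oz_to_grams <- function(oz) {
  if (!is.numeric(oz) || anyNA(oz) || any(oz < 0)) {
    stop_validation("`oz` must be nonnegative.")
  }
  oz * GRAMS_PER_OUNCE
}

#' Read a food composition table
#'
#' The composition table supplies the energy densities needed for
#' calorie-equivalence volume conversion: kcal per cup and kcal per 100 g in
#' the consumed state.
#'
#' @param path Path to a CSV with columns `commodity`, `kcal_per_cup`,
#'   `kcal_per_100g`.
#' @return A tibble validated by [validate_composition()].
#' @export
read_composition <- function(path) {
  comp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_composition(comp)
}

#' Validate a composition table
#'
#' @param comp A data frame with columns `commodity`, `kcal_per_cup`,
#'   `kcal_per_100g`.
#' @return The validated tibble, invisibly usable as input elsewhere.
#' @export
validate_composition <- function(comp) {
  comp <- as_tibble(comp)
  required <- c("commodity", "kcal_per_cup", "kcal_per_100g")
  missing_cols <- setdiff(required, names(comp))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "Composition table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- !is.na(comp$kcal_per_cup) & comp$kcal_per_cup <= 0 |
    !is.na(comp$kcal_per_100g) & comp$kcal_per_100g <= 0
  if (any(bad)) {
    stop_validation(sprintf(
      "Composition table has nonpositive energies for: %s.",
      paste(comp$commodity[bad], collapse = ", ")
    ))
  }
  if (anyDuplicated(comp$commodity)) {
    stop_validation("Composition table has duplicated commodities.")
  }
  comp
}

# Energy-equivalent grams per cup for one commodity, or a missing-reference
# error naming it.
composition_cup_grams <- function(comp, commodity) {
  i <- match(commodity, comp$commodity)
  if (is.na(i) || is.na(comp$kcal_per_cup[i]) || is.na(comp$kcal_per_100g[i])) {
    stop_missing_reference(
      sprintf("No composition entry (kcal per cup / per 100 g) for commodity '%s'.", commodity),
      commodity = commodity
    )
  }
  cup_to_grams(comp$kcal_per_cup[i], comp$kcal_per_100g[i])
}
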