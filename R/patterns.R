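#' Read a commodity supply table
#'
#' Supply tables follow the food-balance-sheet convention: annual per-capita
#' food supply available for human consumption ("apparent consumption"), one
#' row per country and commodity. Dairy supply (agricultural-outlook style)
#' uses the same schema and can simply be row-bound.
#'
#' @param path Path to a CSV with columns `country`, `commodity`, `group`,
#'   `supply_kg_per_capita_yr`, `state`.
#' @return A validated tibble.
#' @export
read_supply_table <- function(path) {
  supply <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_supply_table(supply, source = path)
}

#' Validate a commodity supply table
#'
#' @param supply A data frame in the [read_supply_table()] schema.
#' @param source Optional label (e.g. file path) used in error messages.
#' @return The validated tibble.
#' @export
validate_supply_table <- function(supply, source = "supply table") {
  supply <- as_tibble(supply)
  required <- c("country", "commodity", "group", "supply_kg_per_capita_yr", "state")
  missing_cols <- setdiff(required, names(supply))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "%s is missing column(s): %s.", source, paste(missing_cols, collapse = ", ")
    ))
  }
  bad_state <- !supply$state %in% SUPPLY_STATES
  if (any(bad_state)) {
    stop_validation(sprintf(
      "%s row(s) %s: state must be one of %s.",
      source, paste(which(bad_state), collapse = ", "),
      paste(SUPPLY_STATES, collapse = ", ")
    ))
  }
  bad_supply <- is.na(supply$supply_kg_per_capita_yr) |
    supply$supply_kg_per_capita_yr < 0
  if (any(bad_supply)) {
    stop_validation(sprintf(
      "%s row(s) %s: supply_kg_per_capita_yr must be nonnegative.",
      source, paste(which(bad_supply), collapse = ", ")
    ))
  }
  bad_group <- !supply$group %in% FOOD_GROUPS
  if (any(bad_group)) {
    stop_validation(sprintf(
      "%s row(s) %s: unknown food group(s) %s.",
      source, paste(which(bad_group), collapse = ", "),
      paste(unique(supply$group[bad_group]), collapse = ", ")
    ))
  }
  supply
}

#' Read a conversion-factor table
#'
#' Conversion factors carry supply quantities between processing states
#' (carcass to boneless, shell removal, dry to cooked, raw to cooked) and the
#' cooked-to-raw adjustment used when applying per-kg emission intensities.
#' `direction` declares the physically expected side of 1: `shrink`
#' (factor <= 1, e.g. bone or shell removal, meat cooking loss), `expand`
#' (factor >= 1, e.g. water uptake by grains and legumes), or `free`.
#'
#' @param path Path to a CSV with columns `commodity`, `step`, `factor`,
#'   `direction`.
#' @return A validated tibble usable as a conversion-factor set.
#' @export
read_conversion_factors <- function(path) {
  conv <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_conversion_factors(conv, source = path)
}

#' Validate a conversion-factor table
#'
#' @param conv A data frame in the [read_conversion_factors()] schema.
#' @param source Optional label used in error messages.
#' @return The validated tibble.
#' @export
validate_conversion_factors <- function(conv, source = "conversion table") {
  conv <- as_tibble(conv)
  required <- c("commodity", "step", "factor", "direction")
  missing_cols <- setdiff(required, names(conv))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "%s is missing column(s): %s.", source, paste(missing_cols, collapse = ", ")
    ))
  }
  bad_step <- !conv$step %in% CONVERSION_STEPS
  if (any(bad_step)) {
    stop_validation(sprintf(
      "%s row(s) %s: step must be one of %s.",
      source, paste(which(bad_step), collapse = ", "),
      paste(CONVERSION_STEPS, collapse = ", ")
    ))
  }
  if (any(is.na(conv$factor) | conv$factor <= 0)) {
    stop_validation(sprintf("%s: all factors must be positive.", source))
  }
  bad_dir <- !conv$direction %in% c("shrink", "expand", "free")
  if (any(bad_dir)) {
    stop_validation(sprintf(
      "%s: direction must be 'shrink', 'expand', or 'free'.", source
    ))
  }
  viol <- (conv$direction == "shrink" & conv$factor > 1) |
    (conv$direction == "expand" & conv$factor < 1)
  if (any(viol)) {
    stop_validation(sprintf(
      "%s row(s) %s: factor violates its declared direction.",
      source, paste(which(viol), collapse = ", ")
    ))
  }
  if (anyDuplicated(conv[, c("commodity", "step")])) {
    stop_validation(sprintf("%s: duplicated (commodity, step) pairs.", source))
  }
  conv
}

# Factor for one (commodity, step), or a missing-reference error naming both.
conversion_factor <- function(conv, commodity, step, default = NULL) {
  i <- which(conv$commodity == commodity & conv$step == step)
  if (length(i) == 0L) {
    if (!is.null(default)) {
      return(default)
    }
    stop_missing_reference(
      sprintf("No conversion factor for commodity '%s', step '%s'.", commodity, step),
      commodity = commodity, step = step
    )
  }
  conv$factor[i[1]]
}

#' Default conversion chain for a processing state
#'
#' Maps a supply record's processing state to the ordered conversion steps
#' that bring it to a cooked edible basis: carcass weights are boned out and
#' then cooked; in-shell foods are shelled; dry grains and legumes are cooked
#' (water uptake); raw boneless foods are cooked; `as_is` foods (fruit,
#' vegetables, dairy, oils) need no conversion.
#'
#' @param state One of `carcass`, `raw_in_shell`, `raw_edible`, `dry_raw`,
#'   `as_is`.
#' @return Character vector of step labels (possibly empty).
#' @export
default_chain <- function(state) {
  switch(state,
    carcass = c("carcass_to_boneless", "raw_to_cooked"),
    raw_in_shell = "shell_removal",
    raw_edible = "raw_to_cooked",
    dry_raw = "dry_to_cooked",
    as_is = character(0),
    stop_validation(sprintf("Unknown processing state '%s'.", state))
  )
}

#' Convert supply records to cooked edible mass
#'
#' Applies each record's conversion chain (derived from its processing state,
#' or an explicit `conversion_chain` list-column) to its supply quantity.
#'
#' @param records Supply tibble (see [read_supply_table()]).
#' @param conv Conversion-factor tibble (see [read_conversion_factors()]).
#' @return `records` with an added `cooked_edible_kg` column
#'   (kg/capita/year, cooked edible basis).
#' @export
to_cooked_edible <- function(records, conv) {
  records <- as_tibble(records)
  chains <- if ("conversion_chain" %in% names(records)) {
    records$conversion_chain
  } else {
    lapply(records$state, default_chain)
  }
  records$cooked_edible_kg <- map_dbl(seq_len(nrow(records)), function(i) {
    m <- records$supply_kg_per_capita_yr[i]
    for (step in chains[[i]]) {
      m <- m * conversion_factor(conv, records$commodity[i], step)
    }
    m
  })
  records
}

#' Construct a consumption pattern
#'
#' A consumption pattern holds, for one country and food group, each
#' commodity's share of the group's total cooked-edible mass (the weights of
#' the group's weighted-average emission intensity), plus the share of raw
#' group mass dropped because no emission intensity was available.
#'
#' @param country,group Labels.
#' @param shares Named numeric vector of proportions in `[0, 1]` summing to 1.
#' @param excluded_share Proportion of the group's mass excluded for missing
#'   intensities, in `[0, 1]`.
#' @param tol Tolerance on the share sum (default `1e-9`). Patterns
#'   transcribed from rounded published proportions may need a looser value.
#' @return An object of class `consumption_pattern`.
#' @export
consumption_pattern <- function(country, group, shares, excluded_share = 0,
                                tol = 1e-9) {
  if (length(shares) == 0L || !is.numeric(shares) ||
      is.null(names(shares)) || any(!nzchar(names(shares)))) {
    stop_empty_group(
      sprintf("Pattern for %s/%s has no named shares.", country, group),
      country = country, group = group
    )
  }
  if (any(shares < 0 | shares > 1)) {
    stop_validation("Shares must lie in [0, 1].")
  }
  if (abs(sum(shares) - 1) > tol) {
    stop_validation(sprintf(
      "Shares for %s/%s sum to %.10g, not 1 (tol %g).",
      country, group, sum(shares), tol
    ))
  }
  check_number(excluded_share, "excluded_share", min = 0)
  if (excluded_share > 1) {
    stop_validation("`excluded_share` must be <= 1.")
  }
  structure(
    list(country = country, group = group, shares = shares,
         excluded_share = excluded_share),
    class = "consumption_pattern"
  )
}

#' @export
print.consumption_pattern <- function(x, ...) {
  cat(sprintf(
    "<consumption_pattern> %s/%s: %d commodities (excluded share %.3f)\n",
    x$country, x$group, length(x$shares), x$excluded_share
  ))
  for (nm in names(x$shares)) {
    cat(sprintf("  %-45s %6.3f\n", nm, x$shares[[nm]]))
  }
  invisible(x)
}

#' Derive a consumption pattern from supply records
#'
#' Converts the records for one country and food group to cooked edible
#' weights, drops commodities without an emission intensity (recording the
#' dropped fraction as `excluded_share`), and normalizes the remaining masses
#' to proportions.
#'
#' @param records Supply tibble for a single country and group.
#' @param conv Conversion-factor tibble.
#' @param impacts Impact-factor table (see [impact_factor_table()]).
#' @return A [consumption_pattern()].
#' @export
compute_pattern <- function(records, conv, impacts) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    stop_empty_group("No supply records supplied.")
  }
  country <- unique(records$country)
  group <- unique(records$group)
  if (length(country) != 1L || length(group) != 1L) {
    stop_validation("`records` must cover exactly one country and one group.")
  }
  records <- to_cooked_edible(records, conv)
  records <- records %>%
    group_by(.data$commodity) %>%
    summarise(cooked_edible_kg = sum(.data$cooked_edible_kg), .groups = "drop")
  total <- sum(records$cooked_edible_kg)
  included <- has_impact(impacts, records$commodity)
  included_total <- sum(records$cooked_edible_kg[included])
  if (total <= 0 || included_total <= 0) {
    stop_empty_group(
      sprintf(
        "Group %s/%s has no commodity with positive cooked-edible mass and an emission intensity.",
        country, group
      ),
      country = country, group = group
    )
  }
  shares <- setNames(
    records$cooked_edible_kg[included] / included_total,
    records$commodity[included]
  )
  consumption_pattern(
    country = country, group = group, shares = shares,
    excluded_share = 1 - included_total / total
  )
}

#' Restrict a consumption pattern to an allowed commodity set
#'
#' Used for guidelines whose group covers only a subset of commodities (e.g.
#' plant proteins only): shares outside the allowed set are dropped and the
#' rest renormalized. Idempotent; a superset of the support is the identity.
#'
#' @param p A [consumption_pattern()].
#' @param allowed Character vector of allowed commodities.
#' @return A renormalized `consumption_pattern`.
#' @export
restrict_pattern <- function(p, allowed) {
  stopifnot(inherits(p, "consumption_pattern"))
  keep_names <- intersect(names(p$shares), allowed)
  if (length(keep_names) == 0L) {
    stop_empty_group(
      sprintf(
        "Restricting pattern %s/%s to {%s} leaves no commodities.",
        p$country, p$group, paste(allowed, collapse = ", ")
      ),
      country = p$country, group = p$group
    )
  }
  kept <- p$shares[keep_names]
  consumption_pattern(
    country = p$country, group = p$group,
    shares = kept / sum(kept),
    excluded_share = p$excluded_share
  )
}
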