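#' Build per-commodity recommendation conversions
#'
#' Each commodity's composite conversion factor (its CF) turns a
#' recommendation's unit into kilograms of raw edible commodity, the basis of
#' the emission intensities. Two ingredients feed it: `cup_to_kg`, the
#' calorie-equivalent consumed-state mass of one cup (from the composition
#' table), and `cooked_to_raw`, the raw kg per cooked kg adjustment (from the
#' conversion-factor table; identity for foods the recommendations state in
#' their raw/as-served form, such as fruit, vegetables, and dairy).
#'
#' @param composition Composition table (see [read_composition()]); may be
#'   `NULL` when no guideline uses cup/piece units.
#' @param conv Conversion-factor tibble; rows with step `cooked_to_raw` are
#'   used, all other commodities default to 1.
#' @param commodities Commodities to cover; defaults to the union of those in
#'   `composition` and `conv`.
#' @return A tibble with columns `commodity`, `cup_to_kg`, `cooked_to_raw`.
#' @export
build_commodity_conversions <- function(composition = NULL, conv = NULL,
                                        commodities = NULL) {
  comp_commodities <- if (is.null(composition)) character(0) else composition$commodity
  conv_commodities <- if (is.null(conv)) character(0) else unique(conv$commodity)
  commodities <- commodities %||% union(comp_commodities, conv_commodities)
  cup_to_kg <- map_dbl(commodities, function(cm) {
    if (!is.null(composition) && cm %in% comp_commodities) {
      composition_cup_grams(composition, cm) / 1000
    } else {
      NA_real_
    }
  })
  ctr <- map_dbl(commodities, function(cm) {
    if (is.null(conv)) 1 else conversion_factor(conv, cm, "cooked_to_raw", default = 1)
  })
  tibble(commodity = commodities, cup_to_kg = cup_to_kg, cooked_to_raw = ctr)
}

# CF for one commodity and recommendation unit: kg raw edible per unit.
commodity_cf <- function(conversions, commodity, unit,
                         density = MILK_DENSITY_G_PER_ML) {
  i <- match(commodity, conversions$commodity)
  if (is.na(i)) {
    stop_missing_reference(
      sprintf("No recommendation conversion entry for commodity '%s'.", commodity),
      commodity = commodity
    )
  }
  ctr <- conversions$cooked_to_raw[i]
  per_unit_kg <- switch(unit,
    g = 1e-3,
    oz = GRAMS_PER_OUNCE * 1e-3,
    ml = density * 1e-3,
    cup = ,
    piece = {
      cup_kg <- conversions$cup_to_kg[i]
      if (is.na(cup_kg)) {
        stop_missing_reference(
          sprintf("No cup-to-kg conversion for commodity '%s'.", commodity),
          commodity = commodity, step = "cup_to_kg"
        )
      }
      cup_kg
    },
    serving = stop_validation(
      "Unresolved 'serving' unit: express servings as g, ml, or cup in the config."
    ),
    stop_validation(sprintf("Unknown unit '%s'.", unit))
  )
  per_unit_kg * ctr
}

#' Greenhouse-gas footprint of one food-group recommendation
#'
#' The group footprint is a consumption-weighted average: for each commodity
#' `c` in the group's consumption pattern, the recommended amount is
#' multiplied by the commodity's share of the group, its unit-to-raw-kg
#' conversion factor, and its per-kg emission intensity, and the products are
#' summed:
#' `GHGE_g = sum_c REC_g * Proportion_c * CF_c * GHGE_c`.
#'
#' @param rec_amount Recommended daily amount, in `unit`.
#' @param pattern A [consumption_pattern()] whose shares sum to ~1.
#' @param conversions Per-commodity conversion tibble (see
#'   [build_commodity_conversions()]), or one with a ready-made `cup_to_kg`
#'   column for worked examples.
#' @param impacts Impact-factor table.
#' @param unit Recommendation unit (default `"g"`).
#' @param density Density (g/ml) for `ml` units.
#' @return A list with `ghge` (kg CO2-eq/day) and `contributions`, a tibble
#'   of per-commodity `proportion`, `cf`, `intensity`, and `ghge` that re-sums
#'   to `ghge`.
#' @export
group_footprint <- function(rec_amount, pattern, conversions, impacts,
                            unit = "g", density = MILK_DENSITY_G_PER_ML) {
  check_number(rec_amount, "rec_amount", min = 0)
  stopifnot(inherits(pattern, "consumption_pattern"))
  contributions <- tibble(
    group = pattern$group,
    commodity = names(pattern$shares),
    proportion = unname(pattern$shares),
    cf = map_dbl(names(pattern$shares), commodity_cf,
                 conversions = conversions, unit = unit, density = density),
    intensity = map_dbl(names(pattern$shares), impact_intensity,
                        impacts = impacts)
  )
  contributions$ghge <- rec_amount * contributions$proportion *
    contributions$cf * contributions$intensity
  list(ghge = sum(contributions$ghge), contributions = contributions)
}

#' Allocate discretionary calories pro rata
#'
#' Guidelines that include a discretionary-calorie allowance without
#' specifying its composition are assumed to fill it with the same food mix
#' as the rest of the recommended diet, so the footprint scales up by
#' `diet_kcal / (diet_kcal - discretionary_kcal)`.
#'
#' @param base_total Footprint of the specified recommendations
#'   (kg CO2-eq/day).
#' @param discretionary_kcal Discretionary energy, `0 <= x < diet_kcal`.
#' @param diet_kcal Total diet energy, positive.
#' @return Scaled-up total; equals `base_total` when `discretionary_kcal` is 0.
#' @export
apply_discretionary <- function(base_total, discretionary_kcal, diet_kcal) {
  check_number(base_total, "base_total", min = 0)
  check_number(diet_kcal, "diet_kcal", min = 0, strict = TRUE)
  check_number(discretionary_kcal, "discretionary_kcal", min = 0)
  if (discretionary_kcal >= diet_kcal) {
    stop_validation("`discretionary_kcal` must be smaller than `diet_kcal`.")
  }
  base_total * diet_kcal / (diet_kcal - discretionary_kcal)
}

#' Footprint of a whole guideline set
#'
#' Evaluates every group recommendation of a guideline under the given
#' consumption patterns, adds the sugar add-on (a single-commodity group)
#' when the guideline quantifies sugar, and finally allocates discretionary
#' calories pro rata.
#'
#' Group-level handling:
#' * a recommendation with `allowed_commodities` is evaluated under the
#'   pattern restricted (and renormalized) to that set;
#' * a recommendation with `subgroup_amounts` replaces the pattern weighting
#'   by its fixed per-commodity quantities;
#' * a `sugar` recommendation uses its own single commodity (the
#'   `commodity` field, first allowed commodity, or `"sugar & sweeteners"`).
#'
#' @param gs A [guideline_set()].
#' @param patterns Named list mapping food-group label to
#'   [consumption_pattern()] for the country being evaluated.
#' @param conversions Per-commodity conversion tibble.
#' @param impacts Impact-factor table.
#' @param composition Optional composition table used to resolve cup/piece
#'   recommendations whose commodity conversions lack `cup_to_kg`.
#' @param density Density (g/ml) for `ml` recommendations.
#' @return An object of class `diet_footprint`: country, `per_group` tibble,
#'   `sugar_ghge`, `base_total`, `total` (after discretionary allocation), and
#'   the full `per_commodity` breakdown.
#' @export
diet_footprint <- function(gs, patterns, conversions, impacts,
                           composition = NULL,
                           density = MILK_DENSITY_G_PER_ML) {
  stopifnot(inherits(gs, "guideline_set"))
  recs <- gs$recommendations
  breakdown <- vector("list", nrow(recs))
  group_rows <- vector("list", nrow(recs))
  sugar_ghge <- 0

  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    sg <- rec$subgroup_amounts[[1]]
    allowed <- rec$allowed_commodities[[1]]

    if (rec$group == "sugar") {
      commodity <- if (!is.na(rec$commodity)) {
        rec$commodity
      } else if (!is.null(allowed)) {
        allowed[1]
      } else {
        DEFAULT_SUGAR_COMMODITY
      }
      pattern <- consumption_pattern(
        gs$country, "sugar", setNames(1, commodity)
      )
      res <- group_footprint(rec$amount, pattern, conversions, impacts,
                             unit = rec$unit, density = density)
      sugar_ghge <- res$ghge
      breakdown[[i]] <- res$contributions
      next
    }

    if (!is.null(sg)) {
      # Fixed per-commodity sub-quantities override the pattern weighting.
      contributions <- tibble(
        group = rec$group,
        commodity = names(sg),
        proportion = unname(sg) / sum(sg),
        cf = map_dbl(names(sg), commodity_cf, conversions = conversions,
                     unit = rec$unit, density = density),
        intensity = map_dbl(names(sg), impact_intensity, impacts = impacts)
      )
      contributions$ghge <- unname(sg) * contributions$cf * contributions$intensity
      res <- list(ghge = sum(contributions$ghge), contributions = contributions)
    } else {
      pattern <- patterns[[rec$group]]
      if (is.null(pattern)) {
        stop_missing_reference(
          sprintf("No consumption pattern for group '%s' (%s).",
                  rec$group, gs$country),
          group = rec$group
        )
      }
      if (!is.null(allowed)) {
        pattern <- restrict_pattern(pattern, allowed)
      }
      res <- group_footprint(rec$amount, pattern, conversions, impacts,
                             unit = rec$unit, density = density)
    }
    group_rows[[i]] <- tibble(
      group = rec$group, amount = rec$amount, unit = rec$unit, ghge = res$ghge
    )
    breakdown[[i]] <- res$contributions
  }

  per_group <- bind_rows(group_rows)
  per_commodity <- bind_rows(breakdown)
  base_total <- sum(per_group$ghge) + sugar_ghge
  total <- apply_discretionary(base_total, gs$discretionary_kcal, gs$diet_kcal)
  structure(
    list(
      country = gs$country,
      diet_kcal = gs$diet_kcal,
      discretionary_kcal = gs$discretionary_kcal,
      per_group = per_group,
      sugar_ghge = sugar_ghge,
      base_total = base_total,
      total = total,
      per_commodity = per_commodity
    ),
    class = "diet_footprint"
  )
}

#' @export
print.diet_footprint <- function(x, ...) {
  cat(sprintf("<diet_footprint> %s (%g kcal/d)\n", x$country, x$diet_kcal))
  for (i in seq_len(nrow(x$per_group))) {
    cat(sprintf("  %-22s %6.2f kg CO2-eq/d\n",
                x$per_group$group[i], x$per_group$ghge[i]))
  }
  if (x$sugar_ghge > 0) {
    cat(sprintf("  %-22s %6.2f kg CO2-eq/d\n", "sugar", x$sugar_ghge))
  }
  cat(sprintf("  total %.2f kg CO2-eq/d", x$total))
  if (x$discretionary_kcal > 0) {
    cat(sprintf(" (incl. %g discretionary kcal)", x$discretionary_kcal))
  }
  cat("\n")
  invisible(x)
}

#' Cross-country comparison under one reference consumption pattern
#'
#' Differences between countries' guideline footprints mix two things: the
#' recommendations themselves and each country's own consumption mix within
#' each group. Holding the consumption pattern fixed — evaluating every
#' guideline under a single reference country's patterns — isolates the
#' recommendations. Guidelines whose groups cover only part of the commodity
#' space (via `allowed_commodities`) use the reference pattern restricted and
#' renormalized to that subset.
#'
#' @param guidelines List of [guideline_set()] objects.
#' @param reference_patterns Named list mapping group label to the reference
#'   country's [consumption_pattern()].
#' @param conversions,impacts,composition,density As in [diet_footprint()].
#' @param reference_country Country label whose total anchors the ratio
#'   column; must match one of `guidelines`.
#' @return A tibble with one row per guideline: per-group footprints (wide),
#'   `sugar`, `base_total`, `total`, and `ratio_to_reference` =
#'   reference total / row total. The full `diet_footprint` objects are
#'   attached as attribute `"footprints"`.
#' @export
controlled_comparison <- function(guidelines, reference_patterns, conversions,
                                  impacts, reference_country,
                                  composition = NULL,
                                  density = MILK_DENSITY_G_PER_ML) {
  countries <- map_chr(guidelines, function(g) g$country)
  if (!reference_country %in% countries) {
    stop_validation(sprintf(
      "Reference country '%s' is not among the guidelines (%s).",
      reference_country, paste(countries, collapse = ", ")
    ))
  }
  footprints <- map(guidelines, diet_footprint,
    patterns = reference_patterns, conversions = conversions,
    impacts = impacts, composition = composition, density = density
  )
  tab <- footprint_table(footprints)
  ref_total <- tab$total[match(reference_country, tab$country)]
  tab$ratio_to_reference <- ref_total / tab$total
  attr(tab, "footprints") <- footprints
  tab
}

#' Tabulate diet footprints, one row per country
#'
#' @param footprints List of [diet_footprint()] objects.
#' @return A wide tibble: `country`, one column per food group (kg CO2-eq/d,
#'   `NA` where a guideline lacks the group), `sugar`, `base_total`, `total`,
#'   and flags `has_sugar` / `has_discretionary`.
#' @export
footprint_table <- function(footprints) {
  groups_used <- unique(unlist(map(footprints, function(fp) fp$per_group$group)))
  groups_used <- intersect(FOOD_GROUPS, groups_used)
  rows <- map(footprints, function(fp) {
    vals <- setNames(
      fp$per_group$ghge[match(groups_used, fp$per_group$group)],
      groups_used
    )
    vctrs_row <- c(list(country = fp$country), as.list(vals))
    vctrs_row$sugar <- fp$sugar_ghge
    vctrs_row$base_total <- fp$base_total
    vctrs_row$total <- fp$total
    vctrs_row$has_sugar <- fp$sugar_ghge > 0
    vctrs_row$has_discretionary <- fp$discretionary_kcal > 0
    as_tibble(vctrs_row)
  })
  bind_rows(rows)
}
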