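#' Midpoint of a recommended range
#'
#' Guidelines sometimes state a range (e.g. 1--3 servings); analyses use the
#' midpoint.
#'
#' @param low,high Range bounds, `0 <= low <= high`.
#' @return `(low + high) / 2`. Vectorised.
#' @export
midpoint_amount <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || anyNA(low) || anyNA(high)) {
    stop_validation("`low` and `high` must be non-missing numbers.")
  }
  if (any(low < 0)) {
    stop_validation("`low` must be nonnegative.")
  }
  if (any(high < low)) {
    stop_validation("Range bounds are reversed: `high` must be >= `low`.")
  }
  (low + high) / 2
}

#' Build a single food-group recommendation
#'
#' @param group Food-group label: `protein_foods`, `dairy`, `grains`,
#'   `fruit`, `vegetables`, `oils_fats`, `fruit_and_vegetables`, or `sugar`.
#' @param amount Daily recommended quantity in `unit`, nonnegative.
#' @param unit One of `g`, `ml`, `oz`, `cup`, `piece`, `serving`. Solids are on
#'   a cooked-edible basis, liquids on an as-served volume basis. `serving`
#'   must be resolved to a concrete unit in the guideline config before
#'   analysis; the engine rejects it.
#' @param allowed_commodities Optional character vector restricting the group
#'   to named commodities (e.g. plant proteins only).
#' @param subgroup_amounts Optional named numeric vector fixing per-commodity
#'   sub-quantities that must sum to `amount` within 1%.
#' @param commodity Optional single commodity the recommendation refers to,
#'   used for composition lookups when the unit is `cup`/`piece`.
#' @return A one-row tibble with list-columns for the optional fields.
#' @export
group_recommendation <- function(group, amount, unit,
                                 allowed_commodities = NULL,
                                 subgroup_amounts = NULL,
                                 commodity = NA_character_) {
  if (!is.character(group) || length(group) != 1L || !group %in% FOOD_GROUPS) {
    stop_validation(sprintf(
      "`group` must be one of: %s.", paste(FOOD_GROUPS, collapse = ", ")
    ))
  }
  check_number(amount, "amount", min = 0)
  if (!is.character(unit) || length(unit) != 1L ||
      !unit %in% RECOMMENDATION_UNITS) {
    stop_validation(sprintf(
      "`unit` must be one of: %s.", paste(RECOMMENDATION_UNITS, collapse = ", ")
    ))
  }
  if (!is.null(subgroup_amounts)) {
    if (!is.numeric(subgroup_amounts) || is.null(names(subgroup_amounts)) ||
        any(!nzchar(names(subgroup_amounts)))) {
      stop_validation("`subgroup_amounts` must be a named numeric vector.")
    }
    if (amount > 0 && abs(sum(subgroup_amounts) - amount) > 0.01 * amount) {
      stop_validation(sprintf(
        "Subgroup amounts for '%s' sum to %g, not within 1%% of the group amount %g.",
        group, sum(subgroup_amounts), amount
      ))
    }
  }
  tibble(
    group = group,
    amount = amount,
    unit = unit,
    commodity = commodity,
    allowed_commodities = list(allowed_commodities),
    subgroup_amounts = list(subgroup_amounts)
  )
}

#' Build a guideline set for one country or diet pattern
#'
#' A `guideline_set` bundles one country's food-based dietary guideline: the
#' diet's energy level, the per-group daily recommendations, and any
#' discretionary-calorie allowance (energy with unspecified composition).
#'
#' @param country Label for the country or diet pattern.
#' @param diet_kcal Energy level of the recommended diet (kcal/day), positive.
#' @param recommendations A tibble of rows built with [group_recommendation()]
#'   (or a list of such rows), at most one per group label.
#' @param discretionary_kcal Discretionary energy (kcal/day), `>= 0` and less
#'   than `diet_kcal`.
#' @param notes Optional free-text notes.
#' @return An object of class `guideline_set`.
#' @export
guideline_set <- function(country, diet_kcal, recommendations,
                          discretionary_kcal = 0, notes = NULL) {
  if (!is.character(country) || length(country) != 1L || !nzchar(country)) {
    stop_validation("`country` must be a nonempty string.")
  }
  check_number(diet_kcal, "diet_kcal", min = 0, strict = TRUE)
  check_number(discretionary_kcal, "discretionary_kcal", min = 0)
  if (discretionary_kcal >= diet_kcal) {
    stop_validation("`discretionary_kcal` must be smaller than `diet_kcal`.")
  }
  if (is.data.frame(recommendations)) {
    recs <- as_tibble(recommendations)
  } else {
    recs <- bind_rows(recommendations)
  }
  if (nrow(recs) == 0L) {
    stop_validation("`recommendations` must contain at least one group.")
  }
  if (anyDuplicated(recs$group)) {
    stop_validation("At most one recommendation per food-group label.")
  }
  structure(
    list(
      country = country,
      diet_kcal = diet_kcal,
      discretionary_kcal = discretionary_kcal,
      recommendations = recs,
      notes = notes
    ),
    class = "guideline_set"
  )
}

#' @export
print.guideline_set <- function(x, ...) {
  cat(sprintf(
    "<guideline_set> %s: %g kcal/d (%g discretionary), %d group(s)\n",
    x$country, x$diet_kcal, x$discretionary_kcal, nrow(x$recommendations)
  ))
  for (i in seq_len(nrow(x$recommendations))) {
    cat(sprintf(
      "  %-22s %8.6g %s\n",
      x$recommendations$group[i], x$recommendations$amount[i],
      x$recommendations$unit[i]
    ))
  }
  invisible(x)
}

#' Rescale a guideline set to a target energy level
#'
#' Diet patterns stated at other energy levels (2500 kcal, 2200 kcal, ...) are
#' scaled linearly to a common level, conventionally 2000 kcal: every group
#' amount, every subgroup amount, and the discretionary allowance are
#' multiplied by `target_kcal / diet_kcal`.
#'
#' @param gs A [guideline_set()].
#' @param target_kcal Target energy level (kcal/day), positive.
#' @return A new `guideline_set` at `target_kcal`. Scaling to the set's own
#'   energy level is the identity.
#' @export
scale_guidelines <- function(gs, target_kcal) {
  stopifnot(inherits(gs, "guideline_set"))
  check_number(target_kcal, "target_kcal", min = 0, strict = TRUE)
  ratio <- target_kcal / gs$diet_kcal
  recs <- gs$recommendations
  recs$amount <- recs$amount * ratio
  recs$subgroup_amounts <- lapply(recs$subgroup_amounts, function(sg) {
    if (is.null(sg)) NULL else sg * ratio
  })
  guideline_set(
    country = gs$country,
    diet_kcal = target_kcal,
    recommendations = recs,
    discretionary_kcal = gs$discretionary_kcal * ratio,
    notes = gs$notes
  )
}

#' Resolve a recommendation to grams per day in the consumed state
#'
#' Converts a recommendation's amount to grams/day on the consumed
#' (cooked-edible or as-served) basis: `g` is the identity, `oz` uses
#' 28.3495 g/oz, `ml` uses the commodity density, and `cup`/`piece` use
#' calorie-equivalent grams per cup from the composition table (one piece of
#' fruit is taken as one cup).
#'
#' @param rec A one-row recommendation from [group_recommendation()].
#' @param comp Composition table (see [read_composition()]); required for
#'   `cup`/`piece` units. Lookup key is the recommendation's `commodity` if
#'   set, otherwise its group label.
#' @param density Density in g/ml for `ml` units (default milk, 1.0305).
#' @return Mass in grams/day, consumed state.
#' @export
resolve_recommendation <- function(rec, comp = NULL,
                                   density = MILK_DENSITY_G_PER_ML) {
  rec <- as_tibble(rec)
  stopifnot(nrow(rec) == 1L)
  unit <- rec$unit
  amount <- rec$amount
  switch(unit,
    g = amount,
    oz = oz_to_grams(amount),
    ml = milk_volume_to_mass(amount, density),
    cup = ,
    piece = {
      if (is.null(comp)) {
        stop_missing_reference(sprintf(
          "A composition table is required to resolve '%s' amounts in cups.",
          rec$group
        ))
      }
      key <- if (!is.na(rec$commodity %||% NA_character_)) rec$commodity else rec$group
      amount * composition_cup_grams(comp, key)
    },
    serving = stop_validation(sprintf(
      "Unresolved 'serving' unit for group '%s': serving sizes are country-specific and must be expressed as g, ml, or cup in the guideline config.",
      rec$group
    )),
    stop_validation(sprintf("Unknown unit '%s'.", unit))
  )
}

#' Read a guideline config file
#'
#' Guideline configs are YAML files, one per country, with fields `country`,
#' `diet_kcal`, `discretionary_kcal` (optional), and `recommendations`: a list
#' of `{group, amount, unit, commodity?, allowed_commodities?,
#' subgroup_amounts?}`. Amounts given as `[low, high]` ranges are collapsed to
#' their midpoint.
#'
#' @param path Path to a YAML guideline config.
#' @return A [guideline_set()].
#' @export
read_guideline <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("country", "diet_kcal", "recommendations")) {
    if (is.null(cfg[[field]])) {
      stop_validation(sprintf(
        "Guideline config '%s' is missing field '%s'.", path, field
      ))
    }
  }
  recs <- bind_rows(lapply(cfg$recommendations, function(r) {
    amount <- r$amount
    if (length(amount) == 2L) amount <- midpoint_amount(amount[1], amount[2])
    sga <- r$subgroup_amounts
    if (!is.null(sga)) sga <- unlist(sga)
    group_recommendation(
      group = r$group,
      amount = amount,
      unit = r$unit,
      commodity = r$commodity %||% NA_character_,
      allowed_commodities = unlist(r$allowed_commodities) %||% NULL,
      subgroup_amounts = sga
    )
  }))
  guideline_set(
    country = cfg$country,
    diet_kcal = cfg$diet_kcal,
    recommendations = recs,
    discretionary_kcal = cfg$discretionary_kcal %||% 0,
    notes = cfg$notes %||% NULL
  )
}

#' Write a guideline set to a YAML config file
#'
#' @param gs A [guideline_set()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_guideline <- function(gs, path) {
  stopifnot(inherits(gs, "guideline_set"))
  recs <- lapply(seq_len(nrow(gs$recommendations)), function(i) {
    r <- gs$recommendations[i, ]
    out <- list(group = r$group, amount = r$amount, unit = r$unit)
    if (!is.na(r$commodity)) out$commodity <- r$commodity
    ac <- r$allowed_commodities[[1]]
    if (!is.null(ac)) out$allowed_commodities <- as.list(ac)
    sg <- r$subgroup_amounts[[1]]
    if (!is.null(sg)) out$subgroup_amounts <- as.list(sg)
    out
  })
  cfg <- list(
    country = gs$country,
    diet_kcal = gs$diet_kcal,
    discretionary_kcal = gs$discretionary_kcal,
    recommendations = recs
  )
  if (!is.null(gs$notes)) cfg$notes <- gs$notes
  yaml::write_yaml(cfg, path)
  invisible(path)
}
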