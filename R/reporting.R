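#' Assemble a run configuration
#'
#' Collects the file paths and options a batch run needs. All paths must
#' resolve at run time; validation happens when the bundle is loaded.
#'
#' @param guideline_paths Character vector of guideline YAML configs.
#' @param supply_path,dairy_path Supply CSVs (balance-sheet schema); the
#'   dairy file is optional (`NULL`) and is row-bound onto the supply table.
#' @param conversions_path Conversion-factor CSV.
#' @param impacts_path Emission-intensity CSV.
#' @param composition_path Composition CSV (optional, needed for cup/piece
#'   units).
#' @param target_kcal Energy level all guidelines are scaled to
#'   (default 2000 kcal).
#' @param reference_country Country whose consumption pattern anchors the
#'   controlled comparison.
#' @param output_dir Directory where report CSVs are written (`NULL` to skip
#'   writing).
#' @param density Dairy density in g/ml for ml recommendations.
#' @return A list of class `fbdg_run_config`.
#' @export
run_config <- function(guideline_paths, supply_path, conversions_path,
                       impacts_path, dairy_path = NULL,
                       composition_path = NULL, target_kcal = 2000,
                       reference_country = NULL, output_dir = NULL,
                       density = MILK_DENSITY_G_PER_ML) {
  check_number(target_kcal, "target_kcal", min = 0, strict = TRUE)
  structure(
    list(
      guideline_paths = guideline_paths,
      supply_path = supply_path,
      dairy_path = dairy_path,
      conversions_path = conversions_path,
      impacts_path = impacts_path,
      composition_path = composition_path,
      target_kcal = target_kcal,
      reference_country = reference_country,
      output_dir = output_dir,
      density = density
    ),
    class = "fbdg_run_config"
  )
}

#' Load and validate a study bundle
#'
#' Reads every input named in a [run_config()], scales all guidelines to the
#' target energy level, composes per-commodity recommendation conversions,
#' and derives consumption patterns for every country and group in the
#' supply data (plus a pooled `fruit_and_vegetables` pattern wherever both
#' component groups exist, for guidelines with a combined group).
#'
#' Each commodity dropped for lack of an emission intensity is reported as an
#' audit message (condition class `fbdg_audit`) with its share of the group's
#' mass.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress audit messages about excluded commodities.
#' @return A list with `guidelines` (named list), `patterns` (nested list
#'   country -> group -> [consumption_pattern()]), `conversions`, `impacts`,
#'   `composition`, and `conv_factors`.
#' @export
load_bundle <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "fbdg_run_config"))
  guidelines <- lapply(cfg$guideline_paths, read_guideline)
  guidelines <- lapply(guidelines, scale_guidelines, target_kcal = cfg$target_kcal)
  names(guidelines) <- map_chr(guidelines, function(g) g$country)

  supply <- read_supply_table(cfg$supply_path)
  if (!is.null(cfg$dairy_path)) {
    supply <- bind_rows(supply, read_supply_table(cfg$dairy_path))
  }
  conv_factors <- read_conversion_factors(cfg$conversions_path)
  impacts <- read_impact_table(cfg$impacts_path)
  composition <- if (is.null(cfg$composition_path)) {
    NULL
  } else {
    read_composition(cfg$composition_path)
  }
  conversions <- build_commodity_conversions(
    composition = composition, conv = conv_factors,
    commodities = union(
      supply$commodity,
      union(impacts$commodity,
            if (is.null(composition)) character(0) else composition$commodity)
    )
  )
  patterns <- build_patterns(supply, conv_factors, impacts, quiet = quiet)
  list(
    guidelines = guidelines, patterns = patterns, conversions = conversions,
    impacts = impacts, composition = composition, conv_factors = conv_factors
  )
}

#' Derive consumption patterns for every country and group in a supply table
#'
#' @param supply Supply tibble covering one or more countries.
#' @param conv_factors Conversion-factor tibble.
#' @param impacts Impact-factor table.
#' @param quiet Suppress per-commodity exclusion audit messages.
#' @return Nested named list: `patterns[[country]][[group]]`.
#' @export
build_patterns <- function(supply, conv_factors, impacts, quiet = FALSE) {
  patterns <- list()
  for (ct in unique(supply$country)) {
    ct_supply <- supply %>% filter(.data$country == ct)
    groups <- unique(ct_supply$group)
    patterns[[ct]] <- list()
    for (grp in groups) {
      recs <- ct_supply %>% filter(.data$group == grp)
      audit_exclusions(recs, impacts, quiet = quiet)
      patterns[[ct]][[grp]] <- compute_pattern(recs, conv_factors, impacts)
    }
    # Pooled pattern for guidelines with a single combined fruit+vegetables
    # group: pool the records, then share out as usual.
    if (all(c("fruit", "vegetables") %in% groups) &&
        !"fruit_and_vegetables" %in% groups) {
      pooled <- ct_supply %>%
        filter(.data$group %in% c("fruit", "vegetables")) %>%
        mutate(group = "fruit_and_vegetables")
      patterns[[ct]][["fruit_and_vegetables"]] <-
        compute_pattern(pooled, conv_factors, impacts)
    }
  }
  patterns
}

audit_exclusions <- function(recs, impacts, quiet = FALSE) {
  if (quiet) return(invisible(NULL))
  excluded <- recs$commodity[!has_impact(impacts, recs$commodity)]
  for (cm in excluded) {
    share <- sum(recs$supply_kg_per_capita_yr[recs$commodity == cm]) /
      sum(recs$supply_kg_per_capita_yr)
    inform(
      sprintf(
        "Excluding '%s' (%s/%s): no emission intensity; %.1f%% of the group's raw supply.",
        cm, recs$country[1], recs$group[1], 100 * share
      ),
      class = "fbdg_audit"
    )
  }
  invisible(NULL)
}

round_cols <- function(tab, digits = 2) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  tab
}

#' Baseline report: each guideline under its own consumption pattern
#'
#' Evaluates every guideline in the bundle with its own country's consumption
#' patterns and tabulates per-group and total footprints, one row per
#' guideline in config order. If the config names an output directory, writes
#' `baseline.csv` (cells rounded to 2 decimals) and the full-precision
#' long-format `baseline_breakdown.csv`.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress audit messages.
#' @return The footprint table (full precision), with the `diet_footprint`
#'   objects attached as attribute `"footprints"`.
#' @export
run_baseline <- function(cfg, quiet = FALSE) {
  bundle <- load_bundle(cfg, quiet = quiet)
  if (length(bundle$guidelines) == 0L) {
    warn("No guideline configs supplied; baseline table is empty.")
    return(tibble(country = character(0), total = numeric(0)))
  }
  footprints <- lapply(bundle$guidelines, function(gs) {
    pats <- bundle$patterns[[gs$country]]
    if (is.null(pats)) {
      stop_missing_reference(
        sprintf("No supply data for country '%s'.", gs$country)
      )
    }
    diet_footprint(gs, pats, bundle$conversions, bundle$impacts,
                   composition = bundle$composition, density = cfg$density)
  })
  tab <- footprint_table(footprints)
  attr(tab, "footprints") <- footprints
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(round_cols(tab), file.path(cfg$output_dir, "baseline.csv"))
    breakdown <- bind_rows(lapply(footprints, function(fp) {
      mutate(fp$per_commodity, country = fp$country, .before = 1)
    }))
    readr::write_csv(breakdown,
                     file.path(cfg$output_dir, "baseline_breakdown.csv"))
  }
  tab
}

#' Controlled report: every guideline under the reference pattern
#'
#' Re-evaluates all guidelines under the reference country's consumption
#' patterns and adds the ratio column (reference total / row total). The
#' reference country's own row is identical to its baseline row. Writes
#' `controlled.csv` when the config names an output directory.
#'
#' @param cfg A [run_config()] with a `reference_country`.
#' @param quiet Suppress audit messages.
#' @return The comparison table (full precision; the CSV is rounded to 2
#'   decimals), with footprints attached as attribute `"footprints"`.
#' @export
run_controlled <- function(cfg, quiet = FALSE) {
  if (is.null(cfg$reference_country)) {
    stop_validation("`reference_country` must be set for a controlled run.")
  }
  bundle <- load_bundle(cfg, quiet = quiet)
  ref_patterns <- bundle$patterns[[cfg$reference_country]]
  if (is.null(ref_patterns)) {
    stop_validation(sprintf(
      "Reference country '%s' has no supply data.", cfg$reference_country
    ))
  }
  tab <- controlled_comparison(
    unname(bundle$guidelines), ref_patterns, bundle$conversions,
    bundle$impacts, reference_country = cfg$reference_country,
    composition = bundle$composition, density = cfg$density
  )
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(round_cols(tab), file.path(cfg$output_dir, "controlled.csv"))
  }
  tab
}

#' Validate every file of a study bundle
#'
#' Runs each input file through its schema validator and collects the
#' outcomes instead of stopping at the first failure.
#'
#' @param cfg A [run_config()].
#' @return A tibble with columns `file`, `ok`, `message`; `ok` is `TRUE` for
#'   files that pass.
#' @export
validate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "fbdg_run_config"))
  checks <- c(
    setNames(as.list(cfg$guideline_paths),
             rep("guideline", length(cfg$guideline_paths))),
    list(supply = cfg$supply_path, dairy = cfg$dairy_path,
         conversions = cfg$conversions_path, impacts = cfg$impacts_path,
         composition = cfg$composition_path)
  )
  readers <- list(
    guideline = read_guideline, supply = read_supply_table,
    dairy = read_supply_table, conversions = read_conversion_factors,
    impacts = read_impact_table, composition = read_composition
  )
  rows <- imap(checks, function(path, kind) {
    if (is.null(path)) return(NULL)
    res <- tryCatch(
      {
        readers[[kind]](path)
        tibble(file = path, ok = TRUE, message = "")
      },
      fbdg_error = function(e) tibble(file = path, ok = FALSE,
                                      message = conditionMessage(e)),
      error = function(e) tibble(file = path, ok = FALSE,
                                 message = conditionMessage(e))
    )
    res
  })
  bind_rows(rows)
}
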