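# Synthetic study-bundle generators. These emulate the *structure* of the real
# inputs (balance-sheet supply, agricultural-outlook dairy, per-kg emission
# intensities, conversion factors, composition tables, guideline configs) with
# controlled randomness, so every pipeline stage is testable without the
# non-redistributable source databases. They make no attempt to mimic real
# country profiles statistically.

#' Configuration for the synthetic-data generators
#'
#' @param n_countries Number of synthetic countries (default 7, the study
#'   size this package's examples mirror).
#' @param commodities_per_group Commodities per non-dairy food group
#'   (default 10; with five non-dairy groups plus four dairy products this
#'   yields a vocabulary of comparable size to a real balance-sheet extract).
#' @param share_concentration Concentration of the symmetric Dirichlet
#'   distribution that cooked-edible within-group shares are drawn from
#'   (default 1 = uniform on the simplex).
#' @param intensity_log_mean,intensity_log_sd Log-scale mean and SD of the
#'   lognormal emission-intensity distribution (defaults 0 and 1: median
#'   1 kg CO2-eq/kg with a right tail reaching ruminant-like values).
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 7, commodities_per_group = 10,
                             share_concentration = 1,
                             intensity_log_mean = 0, intensity_log_sd = 1,
                             seed = 1L) {
  check_number(n_countries, "n_countries", min = 1)
  check_number(commodities_per_group, "commodities_per_group", min = 1)
  check_number(share_concentration, "share_concentration", min = 0, strict = TRUE)
  check_number(intensity_log_mean, "intensity_log_mean", min = -Inf)
  check_number(intensity_log_sd, "intensity_log_sd", min = 0)
  check_number(seed, "seed", min = -Inf)
  structure(
    list(
      n_countries = as.integer(n_countries),
      commodities_per_group = as.integer(commodities_per_group),
      share_concentration = share_concentration,
      intensity_log_mean = intensity_log_mean,
      intensity_log_sd = intensity_log_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Symmetric Dirichlet via normalized gammas.
rdirichlet_one <- function(n, alpha) {
  g <- rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n) # degenerate draw guard at tiny alpha
  g / sum(g)
}

synthetic_countries <- function(cfg) {
  sprintf("Synthetia-%02d", seq_len(cfg$n_countries))
}

SYNTH_GROUPS <- c("protein_foods", "grains", "fruit", "vegetables", "oils_fats")
SYNTH_DAIRY <- c("dairy_milk", "dairy_cheese", "dairy_butter", "dairy_yoghurt")

# Cooked-edible kg/capita/year assigned to each group before back-conversion
# to the supply state; magnitudes typical of national balance sheets.
SYNTH_GROUP_TOTALS <- c(
  protein_foods = 35, grains = 110, fruit = 55, vegetables = 75,
  oils_fats = 18, dairy = 120
)

synthetic_commodities <- function(cfg) {
  out <- list()
  for (grp in SYNTH_GROUPS) {
    ids <- sprintf("%s_%02d", grp, seq_len(cfg$commodities_per_group))
    # Protein foods cycle through the processing states a balance sheet mixes:
    # carcass meats, in-shell items, boneless raw fish.
    state <- switch(grp,
      protein_foods = rep(c("carcass", "raw_in_shell", "raw_edible"),
                          length.out = length(ids)),
      grains = rep("dry_raw", length(ids)),
      rep("as_is", length(ids))
    )
    out[[grp]] <- tibble(commodity = ids, group = grp, state = state)
  }
  out$dairy <- tibble(commodity = SYNTH_DAIRY, group = "dairy", state = "as_is")
  bind_rows(out)
}

#' Generate a synthetic conversion-factor table
#'
#' Factors are drawn in physically sensible ranges: bone-out and shell-removal
#' factors below 1, cooking loss for meats below 1, water uptake for grains
#' above 1; the `cooked_to_raw` step is the exact inverse of the cooking step
#' so round-trips are identities.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated conversion-factor tibble
#'   (see [read_conversion_factors()]).
#' @export
gen_conversion_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  commodities <- synthetic_commodities(cfg)
  withr::with_seed(cfg$seed + 3L, {
    rows <- list()
    for (i in seq_len(nrow(commodities))) {
      cm <- commodities$commodity[i]
      st <- commodities$state[i]
      if (st == "carcass") {
        rtc <- runif(1, 0.65, 0.85)
        rows[[length(rows) + 1L]] <- tibble(
          commodity = cm,
          step = c("carcass_to_boneless", "raw_to_cooked", "cooked_to_raw"),
          factor = c(runif(1, 0.55, 0.80), rtc, 1 / rtc),
          direction = c("shrink", "shrink", "expand")
        )
      } else if (st == "raw_in_shell") {
        rows[[length(rows) + 1L]] <- tibble(
          commodity = cm, step = "shell_removal",
          factor = runif(1, 0.40, 0.90), direction = "shrink"
        )
      } else if (st == "raw_edible") {
        rtc <- runif(1, 0.70, 0.90)
        rows[[length(rows) + 1L]] <- tibble(
          commodity = cm,
          step = c("raw_to_cooked", "cooked_to_raw"),
          factor = c(rtc, 1 / rtc),
          direction = c("shrink", "expand")
        )
      } else if (st == "dry_raw") {
        dtc <- runif(1, 2, 3)
        rows[[length(rows) + 1L]] <- tibble(
          commodity = cm,
          step = c("dry_to_cooked", "cooked_to_raw"),
          factor = c(dtc, 1 / dtc),
          direction = c("expand", "shrink")
        )
      }
    }
    validate_conversion_factors(bind_rows(rows), source = "synthetic conversions")
  })
}

#' Generate a synthetic supply table
#'
#' For each country and non-dairy food group, cooked-edible within-group
#' shares are drawn from a symmetric Dirichlet with concentration
#' `share_concentration`, scaled to a realistic group total, and
#' back-converted through each commodity's conversion chain to the processing
#' state a balance sheet reports — so running the forward pipeline recovers
#' exactly the intended shares.
#'
#' @param cfg A [synthetic_config()].
#' @param conv The matching conversion table from [gen_conversion_table()]
#'   (regenerated from `cfg` if omitted).
#' @return A validated supply tibble (see [read_supply_table()]).
#' @export
gen_supply_table <- function(cfg, conv = gen_conversion_table(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  commodities <- synthetic_commodities(cfg) %>% filter(.data$group != "dairy")
  countries <- synthetic_countries(cfg)
  withr::with_seed(cfg$seed + 1L, {
    rows <- list()
    for (ct in countries) {
      for (grp in SYNTH_GROUPS) {
        cms <- commodities %>% filter(.data$group == grp)
        shares <- rdirichlet_one(nrow(cms), cfg$share_concentration)
        cooked <- shares * SYNTH_GROUP_TOTALS[[grp]]
        raw <- map_dbl(seq_len(nrow(cms)), function(i) {
          m <- cooked[i]
          for (step in default_chain(cms$state[i])) {
            m <- m / conversion_factor(conv, cms$commodity[i], step)
          }
          m
        })
        rows[[length(rows) + 1L]] <- tibble(
          country = ct, commodity = cms$commodity, group = grp,
          supply_kg_per_capita_yr = raw, state = cms$state
        )
      }
    }
    validate_supply_table(bind_rows(rows), source = "synthetic supply")
  })
}

#' Generate a synthetic dairy supply table
#'
#' Same schema as [gen_supply_table()] but covering the four dairy products
#' an agricultural-outlook dairy extract reports, all in as-is state.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated supply tibble.
#' @export
gen_dairy_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  countries <- synthetic_countries(cfg)
  withr::with_seed(cfg$seed + 2L, {
    rows <- lapply(countries, function(ct) {
      shares <- rdirichlet_one(length(SYNTH_DAIRY), cfg$share_concentration)
      tibble(
        country = ct, commodity = SYNTH_DAIRY, group = "dairy",
        supply_kg_per_capita_yr = shares * SYNTH_GROUP_TOTALS[["dairy"]],
        state = "as_is"
      )
    })
    validate_supply_table(bind_rows(rows), source = "synthetic dairy supply")
  })
}

#' Generate a synthetic emission-intensity table
#'
#' Intensities are lognormal (strictly positive, right-skewed, like real
#' per-kg emission factors). Named commodities can be withheld to exercise
#' the exclusion/renormalization path.
#'
#' @param cfg A [synthetic_config()].
#' @param withhold Character vector of commodities to leave out of the table.
#' @return A validated impact-factor tibble.
#' @export
gen_impact_table <- function(cfg, withhold = character(0)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  commodities <- c(synthetic_commodities(cfg)$commodity, DEFAULT_SUGAR_COMMODITY)
  withr::with_seed(cfg$seed + 4L, {
    tab <- tibble(
      commodity = commodities,
      kg_co2e_per_kg = rlnorm(length(commodities),
                              meanlog = cfg$intensity_log_mean,
                              sdlog = cfg$intensity_log_sd),
      source_note = "synthetic"
    )
    impact_factor_table(tab %>% filter(!.data$commodity %in% withhold))
  })
}

#' Generate a synthetic composition table
#'
#' Energy densities drawn in group-typical ranges (oils energy-dense, fruit
#' and vegetables dilute), with cup masses between 120 and 250 g so
#' calorie-equivalent cup conversions land in a realistic band.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated composition tibble (see [read_composition()]).
#' @export
gen_composition_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  commodities <- synthetic_commodities(cfg)
  ranges <- list(
    protein_foods = c(120, 280), grains = c(90, 160), fruit = c(35, 95),
    vegetables = c(18, 65), oils_fats = c(700, 900), dairy = c(45, 110)
  )
  withr::with_seed(cfg$seed + 5L, {
    kcal_100g <- map_dbl(commodities$group, function(grp) {
      r <- ranges[[grp]]
      runif(1, r[1], r[2])
    })
    cup_grams <- runif(nrow(commodities), 120, 250)
    validate_composition(tibble(
      commodity = commodities$commodity,
      kcal_per_cup = kcal_100g * cup_grams / 100,
      kcal_per_100g = kcal_100g
    ))
  })
}

#' Generate synthetic guideline sets
#'
#' One guideline per synthetic country, with group amounts drawn across the
#' span the packaged real guidelines cover, every third country carrying a
#' discretionary-calorie allowance and every third a quantified sugar add-on.
#'
#' @param cfg A [synthetic_config()].
#' @return A named list of [guideline_set()] objects.
#' @export
gen_guidelines <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  countries <- synthetic_countries(cfg)
  withr::with_seed(cfg$seed + 6L, {
    sets <- lapply(seq_along(countries), function(i) {
      recs <- bind_rows(
        group_recommendation("protein_foods", runif(1, 75, 170), "g"),
        group_recommendation("dairy", runif(1, 118, 710), "ml"),
        group_recommendation("grains", runif(1, 170, 660), "g"),
        group_recommendation("fruit", runif(1, 100, 780), "g"),
        group_recommendation("vegetables", runif(1, 200, 510), "g"),
        group_recommendation("oils_fats", runif(1, 25, 56), "g")
      )
      if (i %% 3 == 1) {
        recs <- bind_rows(
          recs, group_recommendation("sugar", runif(1, 20, 60), "g")
        )
      }
      disc <- if (i %% 3 == 0) runif(1, 150, 310) else 0
      guideline_set(
        country = countries[i], diet_kcal = 2000,
        recommendations = recs, discretionary_kcal = disc
      )
    })
    setNames(sets, countries)
  })
}

#' Write a complete synthetic study bundle to a directory
#'
#' Emits every input the pipeline consumes — supply, dairy supply, emission
#' intensities, conversion factors, composition, and one guideline config per
#' country — as plain-text files that pass the same schema validation as
#' user-supplied data.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param withhold Commodities to withhold from the impact table.
#' @return A [run_config()] pointing at the written files, with the first
#'   synthetic country as reference.
#' @export
gen_study_bundle <- function(cfg, dir, withhold = character(0)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "guidelines"), showWarnings = FALSE)
  conv <- gen_conversion_table(cfg)
  readr::write_csv(gen_supply_table(cfg, conv), file.path(dir, "supply.csv"))
  readr::write_csv(gen_dairy_table(cfg), file.path(dir, "dairy.csv"))
  readr::write_csv(conv, file.path(dir, "conversions.csv"))
  readr::write_csv(gen_impact_table(cfg, withhold), file.path(dir, "impacts.csv"))
  readr::write_csv(gen_composition_table(cfg), file.path(dir, "composition.csv"))
  guidelines <- gen_guidelines(cfg)
  paths <- map_chr(names(guidelines), function(nm) {
    p <- file.path(dir, "guidelines", paste0(gsub("[^A-Za-z0-9]+", "_", tolower(nm)), ".yaml"))
    write_guideline(guidelines[[nm]], p)
    p
  })
  run_config(
    guideline_paths = paths,
    supply_path = file.path(dir, "supply.csv"),
    dairy_path = file.path(dir, "dairy.csv"),
    conversions_path = file.path(dir, "conversions.csv"),
    impacts_path = file.path(dir, "impacts.csv"),
    composition_path = file.path(dir, "composition.csv"),
    reference_country = synthetic_countries(cfg)[1],
    output_dir = file.path(dir, "out")
  )
}
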