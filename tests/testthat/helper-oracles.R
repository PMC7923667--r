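# Independent brute-force oracles, written against the arithmetic definitions
# only (no calls into the package's own engine paths).

# Weighted-average group footprint: plain per-commodity loop.
oracle_group_footprint <- function(rec_amount, shares, cf, intensity) {
  total <- 0
  for (cm in names(shares)) {
    total <- total + rec_amount * shares[[cm]] * cf[[cm]] * intensity[[cm]]
  }
  total
}

# Within-group shares: per-commodity recount of included and total mass.
oracle_pattern <- function(cooked_mass, included) {
  total_included <- 0
  total <- 0
  for (cm in names(cooked_mass)) {
    total <- total + cooked_mass[[cm]]
    if (included[[cm]]) total_included <- total_included + cooked_mass[[cm]]
  }
  shares <- numeric(0)
  for (cm in names(cooked_mass)) {
    if (included[[cm]]) {
      shares[cm] <- cooked_mass[[cm]] / total_included
    }
  }
  list(shares = shares, excluded_share = 1 - total_included / total)
}

# A minimal single-country supply fixture with mixed processing states.
make_supply_fixture <- function(country = "Testland") {
  tibble::tibble(
    country = country,
    commodity = c("beef", "eggs", "fish", "beans", "apples"),
    group = c("protein_foods", "protein_foods", "protein_foods",
              "protein_foods", "fruit"),
    supply_kg_per_capita_yr = c(20, 10, 8, 5, 40),
    state = c("carcass", "raw_in_shell", "raw_edible", "dry_raw", "as_is")
  )
}

make_conv_fixture <- function() {
  tibble::tibble(
    commodity = c("beef", "beef", "beef", "eggs", "fish", "fish", "beans",
                  "beans"),
    step = c("carcass_to_boneless", "raw_to_cooked", "cooked_to_raw",
             "shell_removal", "raw_to_cooked", "cooked_to_raw",
             "dry_to_cooked", "cooked_to_raw"),
    factor = c(0.7, 0.75, 1 / 0.75, 0.88, 0.8, 1.25, 2.5, 0.4),
    direction = c("shrink", "shrink", "expand", "shrink", "shrink", "expand",
                  "expand", "shrink")
  )
}

make_impacts_fixture <- function(exclude = character(0)) {
  tab <- tibble::tibble(
    commodity = c("beef", "eggs", "fish", "beans", "apples",
                  "sugar & sweeteners"),
    kg_co2e_per_kg = c(30, 4.5, 5.4, 0.8, 0.23, 0.6)
  )
  fbdgcarbon::impact_factor_table(tab[!tab$commodity %in% exclude, ])
}

# Random single-group instance for property tests.
random_pattern_instance <- function(n, seed) {
  withr::with_seed(seed, {
    commodities <- sprintf("c%02d", seq_len(n))
    shares <- rgamma(n, 1)
    shares <- shares / sum(shares)
    list(
      shares = setNames(shares, commodities),
      cf = setNames(runif(n, 0.05, 0.5), commodities),
      intensity = setNames(rlnorm(n, 0, 1), commodities),
      rec_amount = runif(1, 0.5, 10)
    )
  })
}
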