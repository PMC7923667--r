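simple_conversions <- function(shares, cf) {
  tibble::tibble(
    commodity = names(shares),
    cup_to_kg = unname(cf),
    cooked_to_raw = 1
  )
}

test_that("group footprint is the weighted per-commodity sum", {
  # single commodity, share 1, CF 1 kg/unit, intensity 2, rec 1 -> 2
  p <- consumption_pattern("T", "fruit", c(apple = 1))
  conv <- tibble::tibble(commodity = "apple", cup_to_kg = 1, cooked_to_raw = 1)
  impacts <- impact_factor_table(
    tibble::tibble(commodity = "apple", kg_co2e_per_kg = 2)
  )
  expect_equal(group_footprint(1, p, conv, impacts, unit = "cup")$ghge, 2)
  res0 <- group_footprint(0, p, conv, impacts, unit = "cup")
  expect_equal(res0$ghge, 0)
  expect_equal(res0$contributions$ghge, 0)
})

test_that("group footprint equals the brute-force loop oracle", {
  for (seed in 1:30) {
    inst <- random_pattern_instance(8, seed)
    p <- consumption_pattern("T", "grains", inst$shares)
    conv <- simple_conversions(inst$shares, inst$cf)
    impacts <- impact_factor_table(tibble::tibble(
      commodity = names(inst$intensity),
      kg_co2e_per_kg = unname(inst$intensity)
    ))
    res <- group_footprint(inst$rec_amount, p, conv, impacts, unit = "cup")
    expect_equal(
      res$ghge,
      oracle_group_footprint(inst$rec_amount, inst$shares, inst$cf,
                             inst$intensity),
      tolerance = 1e-9
    )
    expect_equal(sum(res$contributions$ghge), res$ghge, tolerance = 1e-12)
  }
})

test_that("per-unit group intensity stays inside the convex-combination bounds", {
  for (seed in 31:50) {
    inst <- random_pattern_instance(6, seed)
    p <- consumption_pattern("T", "grains", inst$shares)
    conv <- simple_conversions(inst$shares, inst$cf)
    impacts <- impact_factor_table(tibble::tibble(
      commodity = names(inst$intensity),
      kg_co2e_per_kg = unname(inst$intensity)
    ))
    ghge <- group_footprint(inst$rec_amount, p, conv, impacts, unit = "cup")$ghge
    per_unit <- ghge / inst$rec_amount
    bounds <- range(inst$cf * inst$intensity)
    expect_gte(per_unit, bounds[1] - 1e-12)
    expect_lte(per_unit, bounds[2] + 1e-12)
  }
})

test_that("missing conversions or intensities fail with named references", {
  p <- consumption_pattern("T", "fruit", c(apple = 0.5, pear = 0.5))
  conv <- tibble::tibble(commodity = "apple", cup_to_kg = 0.1, cooked_to_raw = 1)
  impacts <- impact_factor_table(tibble::tibble(
    commodity = c("apple", "pear"), kg_co2e_per_kg = c(1, 1)
  ))
  err <- expect_error(group_footprint(1, p, conv, impacts, unit = "cup"),
                      class = "fbdg_missing_reference_error")
  expect_match(conditionMessage(err), "pear")
  conv2 <- tibble::tibble(commodity = c("apple", "pear"),
                          cup_to_kg = 0.1, cooked_to_raw = 1)
  impacts2 <- impact_factor_table(tibble::tibble(
    commodity = "apple", kg_co2e_per_kg = 1
  ))
  expect_error(group_footprint(1, p, conv2, impacts2, unit = "cup"),
               class = "fbdg_missing_reference_error")
})

test_that("discretionary-calorie allocation scales pro rata", {
  expect_equal(apply_discretionary(2.5, 0, 2000), 2.5)
  expect_equal(apply_discretionary(1, 1000, 2000), 2)
  expect_error(apply_discretionary(1, 2000, 2000), class = "fbdg_validation_error")
  # increasing in discretionary energy, continuous at zero
  vals <- sapply(c(0, 1, 50, 250, 500), apply_discretionary,
                 base_total = 2, diet_kcal = 2000)
  expect_true(all(diff(vals) > 0))
  expect_equal(apply_discretionary(2, 1e-9, 2000), 2, tolerance = 1e-9)
})

test_that("diet footprint sums groups, sugar, then allocates discretionary", {
  conv <- tibble::tibble(
    commodity = c("beef", "beans", "wheat", "sugar & sweeteners"),
    cup_to_kg = NA_real_,
    cooked_to_raw = c(4 / 3, 0.4, 0.4, 1)
  )
  impacts <- impact_factor_table(tibble::tibble(
    commodity = c("beef", "beans", "wheat", "sugar & sweeteners"),
    kg_co2e_per_kg = c(30, 0.8, 0.5, 0.6)
  ))
  patterns <- list(
    protein_foods = consumption_pattern("T", "protein_foods",
                                        c(beef = 0.7, beans = 0.3)),
    grains = consumption_pattern("T", "grains", c(wheat = 1))
  )
  gs <- guideline_set(
    "T", 2000,
    dplyr::bind_rows(
      group_recommendation("protein_foods", 150, "g"),
      group_recommendation("grains", 200, "g"),
      group_recommendation("sugar", 30, "g")
    ),
    discretionary_kcal = 250
  )
  fp <- diet_footprint(gs, patterns, conv, impacts)

  # hand-computed: protein 0.150*(0.7*(4/3)*30 + 0.3*0.4*0.8)
  protein <- 0.150 * (0.7 * (4 / 3) * 30 + 0.3 * 0.4 * 0.8)
  grains <- 0.200 * 0.4 * 0.5
  sugar <- 0.030 * 0.6
  expect_equal(fp$per_group$ghge[fp$per_group$group == "protein_foods"],
               protein, tolerance = 1e-12)
  expect_equal(fp$per_group$ghge[fp$per_group$group == "grains"], grains)
  expect_equal(fp$sugar_ghge, sugar)
  expect_equal(fp$base_total, protein + grains + sugar, tolerance = 1e-12)
  expect_equal(fp$total, fp$base_total * 2000 / 1750, tolerance = 1e-12)
  # the commodity breakdown re-sums to the group values
  resum <- tapply(fp$per_commodity$ghge, fp$per_commodity$group, sum)
  expect_equal(unname(resum["protein_foods"]), protein, tolerance = 1e-9)
  expect_equal(sum(fp$per_commodity$ghge), fp$base_total, tolerance = 1e-9)

  # doubling every recommendation doubles the base total exactly
  gs2 <- gs
  gs2$recommendations$amount <- gs2$recommendations$amount * 2
  expect_equal(diet_footprint(gs2, patterns, conv, impacts)$base_total,
               2 * fp$base_total, tolerance = 1e-12)

  # all-zero guideline -> all-zero footprint
  gs0 <- gs
  gs0$recommendations$amount <- 0
  fp0 <- diet_footprint(gs0, patterns, conv, impacts)
  expect_equal(fp0$total, 0)
  expect_equal(fp0$per_group$ghge, rep(0, 2))
})

test_that("fixed subgroup amounts override the pattern weighting", {
  conv <- tibble::tibble(
    commodity = c("beef", "beans"), cup_to_kg = NA_real_,
    cooked_to_raw = c(1.25, 0.4)
  )
  impacts <- impact_factor_table(tibble::tibble(
    commodity = c("beef", "beans"), kg_co2e_per_kg = c(30, 0.8)
  ))
  gs <- guideline_set("T", 2000, group_recommendation(
    "protein_foods", 100, "g", subgroup_amounts = c(beef = 40, beans = 60)
  ))
  fp <- diet_footprint(gs, patterns = list(), conv, impacts)
  expect_equal(fp$base_total,
               0.040 * 1.25 * 30 + 0.060 * 0.4 * 0.8, tolerance = 1e-12)
})

test_that("restricted groups use the renormalized pattern", {
  conv <- tibble::tibble(
    commodity = c("beef", "beans", "peas"), cup_to_kg = NA_real_,
    cooked_to_raw = 1
  )
  impacts <- impact_factor_table(tibble::tibble(
    commodity = c("beef", "beans", "peas"), kg_co2e_per_kg = c(30, 0.8, 0.9)
  ))
  patterns <- list(protein_foods = consumption_pattern(
    "T", "protein_foods", c(beef = 0.5, beans = 0.3, peas = 0.2)
  ))
  gs <- guideline_set("T", 2000, group_recommendation(
    "protein_foods", 100, "g", allowed_commodities = c("beans", "peas")
  ))
  fp <- diet_footprint(gs, patterns, conv, impacts)
  expect_equal(fp$base_total, 0.1 * (0.6 * 0.8 + 0.4 * 0.9), tolerance = 1e-12)
})

test_that("controlled comparison anchors on the reference country", {
  conv <- tibble::tibble(commodity = c("a", "b"), cup_to_kg = NA_real_,
                         cooked_to_raw = 1)
  impacts <- impact_factor_table(tibble::tibble(
    commodity = c("a", "b"), kg_co2e_per_kg = c(2, 10)
  ))
  ref_patterns <- list(fruit = consumption_pattern(
    "Ref", "fruit", c(a = 0.25, b = 0.75)
  ))
  gs_ref <- guideline_set("Ref", 2000, group_recommendation("fruit", 100, "g"))
  gs_other <- guideline_set("Other", 2000, group_recommendation("fruit", 300, "g"))
  tab <- controlled_comparison(list(gs_ref, gs_other), ref_patterns, conv,
                               impacts, reference_country = "Ref")
  direct <- diet_footprint(gs_ref, ref_patterns, conv, impacts)
  expect_identical(tab$total[tab$country == "Ref"], direct$total)
  expect_equal(tab$ratio_to_reference[tab$country == "Ref"], 1)
  expect_equal(tab$ratio_to_reference[tab$country == "Other"],
               direct$total / diet_footprint(gs_other, ref_patterns, conv,
                                             impacts)$total)
  # two identical guidelines -> ratio exactly 1
  gs_twin <- guideline_set("Twin", 2000, group_recommendation("fruit", 100, "g"))
  tab2 <- controlled_comparison(list(gs_ref, gs_twin), ref_patterns, conv,
                                impacts, reference_country = "Ref")
  expect_equal(tab2$ratio_to_reference, c(1, 1))
  expect_error(
    controlled_comparison(list(gs_ref), ref_patterns, conv, impacts,
                          reference_country = "Elsewhere"),
    class = "fbdg_validation_error"
  )
})
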