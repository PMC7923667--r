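test_that("range midpoints are forced arithmetic with validated bounds", {
  expect_equal(midpoint_amount(1, 3), 2)
  expect_equal(midpoint_amount(5, 5), 5)
  expect_equal(midpoint_amount(0, 2.5), 1.25)
  for (m in c(0, 0.5, 7, 123.4)) expect_equal(midpoint_amount(m, m), m)
  expect_error(midpoint_amount(3, 1), class = "fbdg_validation_error")
  expect_error(midpoint_amount(-1, 3), class = "fbdg_validation_error")
})

make_gs <- function(diet_kcal = 2500, amount = 100, disc = 0, sg = NULL) {
  guideline_set(
    country = "Testland", diet_kcal = diet_kcal,
    recommendations = group_recommendation(
      "protein_foods", amount, "g", subgroup_amounts = sg
    ),
    discretionary_kcal = disc
  )
}

test_that("energy scaling is linear in every quantity", {
  # 2500-kcal pattern scaled to 2000: x0.8
  gs <- make_gs(2500, 100, disc = 125, sg = c(beef = 40, beans = 60))
  scaled <- scale_guidelines(gs, 2000)
  expect_equal(scaled$diet_kcal, 2000)
  expect_equal(scaled$recommendations$amount, 80)
  expect_equal(scaled$recommendations$subgroup_amounts[[1]],
               c(beef = 32, beans = 48))
  expect_equal(scaled$discretionary_kcal, 100)
  # identity at the set's own level
  expect_equal(scale_guidelines(gs, 2500)$recommendations$amount, 100)
  # 2200-kcal pattern with 55 g -> 50 g
  expect_equal(scale_guidelines(make_gs(2200, 55), 2000)$recommendations$amount, 50)
  expect_error(scale_guidelines(gs, 0), class = "fbdg_validation_error")
})

test_that("scaling is homogeneous of degree one and composes", {
  gs <- make_gs(2200, 137.5, disc = 80)
  for (k in c(0.5, 1, 1.7)) {
    direct <- scale_guidelines(gs, 2000 * k)
    expect_equal(direct$recommendations$amount,
                 scale_guidelines(gs, 2000)$recommendations$amount * k,
                 tolerance = 1e-9)
  }
  composed <- scale_guidelines(scale_guidelines(gs, 2500), 2000)
  direct <- scale_guidelines(gs, 2000)
  expect_equal(composed$recommendations$amount, direct$recommendations$amount,
               tolerance = 1e-9)
  expect_equal(composed$discretionary_kcal, direct$discretionary_kcal,
               tolerance = 1e-9)
})

test_that("recommendations resolve to consumed-state grams per day", {
  comp <- validate_composition(tibble::tibble(
    commodity = "black beans", kcal_per_cup = 662, kcal_per_100g = 341
  ))
  beans2c <- group_recommendation("protein_foods", 2, "cup",
                                  commodity = "black beans")
  expect_equal(round(resolve_recommendation(beans2c, comp)), 388)
  expect_equal(resolve_recommendation(group_recommendation("grains", 100, "g")), 100)
  expect_equal(resolve_recommendation(group_recommendation("protein_foods", 1, "oz")),
               28.3495)
  expect_equal(resolve_recommendation(group_recommendation("dairy", 710, "ml")),
               731.655)
  # one piece of fruit is one cup of fruit
  fruit_comp <- validate_composition(tibble::tibble(
    commodity = "fruit", kcal_per_cup = 98, kcal_per_100g = 50
  ))
  expect_equal(
    resolve_recommendation(group_recommendation("fruit", 3, "piece"), fruit_comp),
    resolve_recommendation(group_recommendation("fruit", 3, "cup"), fruit_comp)
  )
  # linearity in amount
  one <- resolve_recommendation(group_recommendation(
    "protein_foods", 1, "cup", commodity = "black beans"), comp)
  five <- resolve_recommendation(group_recommendation(
    "protein_foods", 5, "cup", commodity = "black beans"), comp)
  expect_equal(five, 5 * one, tolerance = 1e-12)
  expect_error(
    resolve_recommendation(group_recommendation("grains", 6, "serving")),
    class = "fbdg_validation_error"
  )
  err <- expect_error(
    resolve_recommendation(
      group_recommendation("fruit", 1, "cup", commodity = "durian"), comp
    ),
    class = "fbdg_missing_reference_error"
  )
  expect_match(conditionMessage(err), "durian")
})

test_that("guideline-set invariants are enforced", {
  expect_error(
    guideline_set("X", 2000, dplyr::bind_rows(
      group_recommendation("fruit", 100, "g"),
      group_recommendation("fruit", 200, "g")
    )),
    class = "fbdg_validation_error"
  )
  expect_error(make_gs(2000, 100, disc = 2000), class = "fbdg_validation_error")
  expect_error(
    group_recommendation("protein_foods", 100, "g",
                         subgroup_amounts = c(beef = 50, beans = 30)),
    class = "fbdg_validation_error"
  )
  expect_error(group_recommendation("protein_foods", -1, "g"),
               class = "fbdg_validation_error")
  expect_error(group_recommendation("snacks", 10, "g"),
               class = "fbdg_validation_error")
})

test_that("guideline configs round-trip through YAML and collapse ranges", {
  gs <- guideline_set(
    country = "Roundtripia", diet_kcal = 2200, discretionary_kcal = 150,
    recommendations = dplyr::bind_rows(
      group_recommendation("protein_foods", 120, "g",
                           allowed_commodities = c("beans", "peas"),
                           subgroup_amounts = c(beans = 70, peas = 50)),
      group_recommendation("dairy", 400, "ml"),
      group_recommendation("sugar", 30, "g")
    )
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_guideline(gs, path)
  back <- read_guideline(path)
  expect_equal(back$country, gs$country)
  expect_equal(back$diet_kcal, gs$diet_kcal)
  expect_equal(back$discretionary_kcal, gs$discretionary_kcal)
  expect_equal(back$recommendations$amount, gs$recommendations$amount)
  expect_equal(back$recommendations$allowed_commodities[[1]], c("beans", "peas"))
  expect_equal(back$recommendations$subgroup_amounts[[1]],
               c(beans = 70, peas = 50))

  # a [low, high] amount in the config is collapsed to its midpoint
  ranged <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "country: Rangeland",
    "diet_kcal: 2000",
    "recommendations:",
    "- group: fruit",
    "  amount: [200, 300]",
    "  unit: g"
  ), ranged)
  expect_equal(read_guideline(ranged)$recommendations$amount, 250)
})
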