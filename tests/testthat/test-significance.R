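specs <- nutrient_specs()

test_that("thresholds are exact fractions of the DRI for all four nutrients", {
  tab <- significance_thresholds(specs)
  expect_equal(tab$beverage_threshold, 0.075 * tab$dri)
  expect_equal(tab$solid_threshold, 0.15 * tab$dri)
  # beverage cutoff is exactly half the solid cutoff
  expect_equal(tab$beverage_threshold, tab$solid_threshold / 2)

  get <- function(nu, col) tab[[col]][tab$nutrient_id == nu]
  expect_identical(get("folic_acid", "beverage_threshold"), 15)
  expect_identical(get("folic_acid", "solid_threshold"), 30)
  expect_identical(get("vitamin_b12", "beverage_threshold"), 0.1875)
  expect_identical(get("vitamin_b12", "solid_threshold"), 0.375)
  expect_identical(get("calcium", "beverage_threshold"), 60)
  expect_identical(get("calcium", "solid_threshold"), 120)
  expect_identical(get("zinc", "beverage_threshold"), 0.75)
  expect_identical(get("zinc", "solid_threshold"), 1.5)
})

test_that("equality at the cutoff is significant; below is not", {
  ca <- spec_for("calcium")
  zn <- spec_for("zinc")
  expect_true(is_significant(120, ca, beverage = FALSE))
  expect_false(is_significant(119.999, ca, beverage = FALSE))
  expect_true(is_significant(60, ca, beverage = TRUE))
  expect_false(is_significant(0.74, zn, beverage = TRUE))
  expect_true(is_significant(0.75, zn, beverage = TRUE))
  expect_true(is_significant(30, spec_for("folic_acid"), beverage = FALSE))
})

test_that("significance is monotone in the declared value", {
  for (nu in specs$nutrient_id) {
    sp <- spec_for(nu)
    for (bev in c(TRUE, FALSE)) {
      v <- sort(runif(50, 0, 3 * sp$solid_threshold))
      s <- is_significant(v, sp, bev)
      expect_true(all(diff(as.integer(s)) >= 0))
    }
  }
})

test_that("beverage membership is categorical on group and subgroup", {
  recs <- tibble::tibble(
    food_group = c("Drinks", "Bread", "Milk, milk products, and milk replacers",
                   "Milk, milk products, and milk replacers", NA),
    food_subgroup = c(NA, NA, "dairy drinks", "cheese spreads", NA)
  )
  expect_equal(is_beverage(recs), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # no inference from names: a water called "bronwater" in an eligible
  # non-beverage group stays non-beverage
  expect_false(is_beverage(tibble::tibble(food_group = "Soup",
                                          food_name = "bronwater")))
})
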