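cfg <- fortification_config()
specs <- cfg$specs

test_that("step 1 routes ineligible groups and unclassified foods", {
  recs <- dplyr::bind_rows(
    make_record("a", food_group = "Foods and formulae for infants and young children"),
    make_record("b", food_group = NA_character_),
    make_record("c", food_group = "Cereals and cereal products"),
    make_record("d", food_group = "Food supplements")
  )
  expect_equal(step1_eligible(recs),
               c("ineligible", "ineligible", "eligible", "ineligible"))
  # unclassified foods can be kept eligible by configuration
  keep <- eligibility_rule(treat_unclassified_as_ineligible = FALSE)
  expect_equal(step1_eligible(recs, keep)[2], "eligible")
})

test_that("step 2 distinguishes absent values from explicit zeros, with the DFE rule", {
  r_present <- make_record("a", vitamin_b12 = 1.0)
  r_absent <- make_record("b")
  r_zero <- make_record("c", vitamin_b12 = 0)
  expect_equal(step2_value_declared(r_present, "vitamin_b12"), "to_step3")
  expect_equal(step2_value_declared(r_absent, "vitamin_b12"), "to_step7")
  expect_equal(step2_value_declared(r_zero, "vitamin_b12"), "to_step3")
  # an explicit zero is a present, insignificant value: step 3 diverts it
  expect_equal(step3_significant(r_zero, "vitamin_b12"), "to_step7")

  # folate: DFE stands in for the folic-acid column, and wins when both exist
  expect_equal(step2_value_declared(make_record("d", dfe = 40), "folic_acid"),
               "to_step3")
  expect_equal(effective_value(make_record("e", dfe = 40, folic_acid = 10),
                               "folic_acid"), 40)
  expect_equal(effective_value(make_record("f", folic_acid = 10), "folic_acid"), 10)
})

test_that("step 3 applies the beverage-aware cutoffs", {
  solid <- make_record("a", food_group = "Bread", calcium = 130)
  expect_equal(step3_significant(solid, "calcium"), "to_step4")
  # 60 is the beverage cutoff: significant in a drink, not in a solid food
  expect_equal(step3_significant(make_record("b", food_group = "Bread",
                                             calcium = 60), "calcium"),
               "to_step7")
  expect_equal(step3_significant(make_record("c", food_group = "Drinks",
                                             calcium = 60), "calcium"),
               "to_step4")
  expect_equal(step3_significant(make_record("d", food_group = "Drinks",
                                             zinc = 0.75), "zinc"), "to_step4")
})

test_that("steps 4-6 route on ingredient-list matches and their context", {
  b12 <- make_record("a", ingredient_list = "water, cyanocobalamine",
                     vitamin_b12 = 1)
  expect_equal(step4_term_in_ingredients(b12, "vitamin_b12"), "to_step6")
  expect_equal(step4_term_in_ingredients(
    make_record("b", ingredient_list = "water, suiker", vitamin_b12 = 1),
    "vitamin_b12"), "to_step5")
  expect_equal(step4_term_in_ingredients(make_record("c", vitamin_b12 = 1),
                                         "vitamin_b12"), "to_step5")

  expect_equal(step5_generic_terms(
    make_record("d", ingredient_list = "water, vitaminen en mineralen"),
    "vitamin_b12"), "fortified")
  expect_equal(step5_generic_terms(
    make_record("e", ingredient_list = "water"), "vitamin_b12"), "to_step7")
  # a qualified generic word does not rescue
  expect_equal(step5_generic_terms(
    make_record("f", ingredient_list = "water, vitamine c"), "calcium"),
    "to_step7")

  expect_equal(step6_additive_or_natural(
    make_record("g", ingredient_list = "stabilisator (calciumcarbonaat)"),
    "calcium"), "to_step7")
  expect_equal(step6_additive_or_natural(
    make_record("h", ingredient_list = "melk, rijk aan calcium"), "calcium"),
    "non_fortified")
  expect_equal(step6_additive_or_natural(
    make_record("i", ingredient_list = "melk, calciumcarbonaat"), "calcium"),
    "fortified")
  # plain fortificant match wins over a parallel additive-context match
  expect_equal(step6_additive_or_natural(
    make_record("j", ingredient_list =
                  "stabilisator (calciumcarbonaat), calciumlactaat"),
    "calcium"), "fortified")
})

test_that("step 7 needs a term plus wording; bare phrases never classify fortified", {
  expect_equal(step7_label_text(
    make_record("a", legal_name = "halvarine verrijkt met foliumzuur"),
    "folic_acid"), "fortified")
  expect_equal(step7_label_text(
    make_record("b", mandatory_particulars = "bron van calcium"), "calcium"),
    "non_fortified")
  expect_equal(step7_label_text(make_record("c"), "calcium"), "non_fortified")
  # wording without any term was removed from the procedure for a reason
  expect_equal(step7_label_text(
    make_record("d", legal_name = "verrijkt met extra goeds"), "calcium"),
    "non_fortified")
  # food names are not searched unless asked
  expect_equal(step7_label_text(
    make_record("e", food_name = "drank verrijkt met calcium"), "calcium"),
    "non_fortified")
  cfg_fn <- fortification_config(search_food_name = TRUE)
  expect_equal(step7_label_text(
    make_record("f", food_name = "drank verrijkt met calcium"), "calcium",
    cfg_fn), "fortified")
})

test_that("documented end-to-end cases classify as the procedure would", {
  recs <- dplyr::bind_rows(
    # mineral water: natural calcium spelled out -> procedure-fortified
    make_record("water", food_group = "Drinks",
                ingredient_list = "natuurlijk mineraalwater (calcium 80 mg/l, magnesium 25 mg/l)",
                calcium = 80),
    # meat substitute with B12 declared below significance
    make_record("meat", food_group = "Meat replacers",
                ingredient_list = "water, erwteneiwit, vitamine b12",
                vitamin_b12 = 0.2),
    # fortified-with-everything infant formula stays ineligible
    make_record("infant",
                food_group = "Foods and formulae for infants and young children",
                ingredient_list = "melkpoeder, calciumcarbonaat, cyanocobalamine",
                calcium = 200, vitamin_b12 = 1, zinc = 3, folic_acid = 80)
  )
  res <- classify_foods(recs, cfg)
  expect_equal(label_of(res, "water", "calcium"), "fortified")
  expect_equal(label_of(res, "meat", "vitamin_b12"), "non_fortified")
  for (nu in specs$nutrient_id) {
    expect_equal(label_of(res, "infant", nu), "ineligible")
  }
})

test_that("every trace replays to its label and is a strictly increasing path", {
  corpus <- generate_corpus(synth_config(seed = 21, typo_prob = 0.05))
  res <- classify_foods(corpus$records, cfg)
  expect_true(all(vapply(seq_len(nrow(res)), function(i) {
    tr <- res$trace[[i]]
    tr$step[1] == 1L && all(diff(tr$step) > 0) &&
      replay_trace(tr) == as.character(res$label[i])
  }, logical(1))))
  # ineligible exactly when the trace ends at step 1
  ends1 <- vapply(res$trace, function(tr) length(tr$step) == 1L, logical(1))
  expect_equal(ends1, as.character(res$label) == "ineligible")
})

test_that("labels partition the dataset and the step tally satisfies the tree identity", {
  corpus <- generate_corpus(synth_config(seed = 31))
  res <- classify_foods(corpus$records, cfg, trace = FALSE)
  tally <- step_tally(res)
  expect_equal(tally$fortified + tally$non_fortified + tally$ineligible,
               rep(nrow(corpus$records), nrow(tally)))
  expect_true(all(tally$identity_ok))
  # empty dataset: empty results
  empty <- classify_foods(make_record("x")[0, ], cfg, trace = FALSE)
  expect_equal(nrow(empty), 0)
})

test_that("raising a declared value never turns fortified into anything else", {
  corpus <- generate_corpus(synth_config(seed = 41))
  recs <- corpus$records
  res1 <- classify_foods(recs, cfg, trace = FALSE)
  boosted <- dplyr::mutate(recs, dplyr::across(
    dplyr::all_of(c("calcium", "folic_acid", "dfe", "vitamin_b12", "zinc")),
    ~ .x * 5
  ))
  res2 <- classify_foods(boosted, cfg, trace = FALSE)
  was_fortified <- as.character(res1$label) == "fortified"
  expect_true(all(as.character(res2$label)[was_fortified] == "fortified"))
})

test_that("classification rejects duplicate ids and unknown nutrients", {
  dup <- dplyr::bind_rows(make_record("a"), make_record("a"))
  expect_error(classify_foods(dup, cfg), "unique")
  expect_error(classify_foods(make_record("a"), cfg, nutrients = "iron"),
               "not in configuration")
})
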