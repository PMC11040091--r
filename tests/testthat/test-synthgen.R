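test_that("a fixed seed reproduces the corpus byte for byte", {
  cfg <- synth_config(seed = 99, typo_prob = 0.1)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$ground_truth, c2$ground_truth)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_food_records(c1$records, p1)
  write_food_records(c2$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  c3 <- generate_corpus(synth_config(seed = 100, typo_prob = 0.1))
  expect_false(identical(c1$records$ingredient_list,
                         c3$records$ingredient_list))
})

test_that("scenario bookkeeping matches its construction", {
  cfg <- synth_config(n = c(clean_fortified = 50), seed = 5)
  corpus <- generate_corpus(cfg)
  expect_equal(nrow(corpus$records), 50)
  gt <- corpus$ground_truth
  # every record fortified for exactly one nutrient, by both labels
  per_food <- dplyr::summarise(
    dplyr::group_by(gt, food_id),
    n_fort_truth = sum(truth == "fortified"),
    n_fort_exp = sum(expected == "fortified"), .groups = "drop"
  )
  expect_true(all(per_food$n_fort_truth == 1))
  expect_true(all(per_food$n_fort_exp == 1))
  expect_true(all(gt$compliant))

  # mineral-water baits are always expected-fortified / truth-non-fortified
  baits <- generate_corpus(synth_config(n = c(mineral_water = 8), seed = 6))
  bc <- baits$ground_truth[baits$ground_truth$nutrient == "calcium", ]
  expect_true(all(bc$expected == "fortified"))
  expect_true(all(bc$truth == "non_fortified"))
  ec <- expected_confusion(baits)
  expect_equal(unclass(ec$calcium)["non_fortified", "fortified"], 8L)

  # mis-filed ineligible foods land in the expert-ineligible row
  mis <- generate_corpus(synth_config(n = c(misfiled_ineligible = 7), seed = 8))
  em <- expected_confusion(mis)
  fort_cells <- sum(vapply(em, function(m) unclass(m)["ineligible", "fortified"], 0L))
  expect_equal(fort_cells, 14L)  # two fortified nutrients per mis-filed food

  expect_error(synth_config(n = c(unicorns = 3)), "Unknown scenario")
  expect_error(synth_config(n = c(clean_fortified = 0)), "infeasible")
})

test_that("an all-clean corpus is classified perfectly, by construction", {
  corpus <- generate_corpus(synth_config(n = c(clean_fortified = 60), seed = 13))
  res <- classify_foods(corpus$records, trace = FALSE)
  cmp <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(res), food_id, nutrient, label),
    corpus$ground_truth, by = c("food_id", "nutrient")
  )
  expect_true(all(as.character(cmp$label) == cmp$truth))
  ec <- expected_confusion(corpus)
  for (m in ec) {
    mm <- unclass(m)
    expect_equal(sum(mm) - sum(diag(mm)), 0L)
  }
})

test_that("typo corruption yields truth-fortified, expected-non-fortified records", {
  corpus <- generate_corpus(synth_config(n = c(clean_fortified = 120),
                                         typo_prob = 0.5, seed = 17))
  gt <- corpus$ground_truth
  typo <- gt[gt$scenario == "typo", ]
  expect_gt(nrow(typo), 0)
  flipped <- typo[typo$truth == "fortified", ]
  expect_true(all(flipped$expected == "non_fortified"))
  expect_true(all(!typo$compliant))
  # and the classifier indeed misses them (the documented failure mode)
  res <- classify_foods(corpus$records, trace = FALSE)
  cmp <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(res), food_id, nutrient, label),
    flipped, by = c("food_id", "nutrient")
  )
  expect_true(all(as.character(cmp$label) == "non_fortified"))
})

test_that("generated records survive CSV round-trips losslessly", {
  corpus <- generate_corpus(synth_config(seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_records(corpus$records, path)
  back <- read_food_records(path)
  expect_equal(as.data.frame(back), as.data.frame(corpus$records))
  # absent values stay absent (not zero) through the round-trip
  expect_identical(is.na(back$calcium), is.na(corpus$records$calcium))
})
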