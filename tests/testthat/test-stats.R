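test_that("contingency tables count expert-vs-procedure pairs in fixed order", {
  tab <- build_contingency(
    c("fortified", "fortified", "non_fortified", "ineligible"),
    c("fortified", "non_fortified", "non_fortified", "ineligible")
  )
  expect_equal(unclass(tab)["fortified", "fortified"], 1L)
  expect_equal(unclass(tab)["fortified", "non_fortified"], 1L)
  expect_equal(rownames(tab), c("fortified", "non_fortified", "ineligible"))

  diag_tab <- build_contingency(rep("fortified", 3), rep("fortified", 3))
  expect_equal(sum(unclass(diag_tab)), 3L)
  expect_equal(unclass(diag_tab)[1, 1], 3L)

  empty <- build_contingency(character(), character())
  expect_true(all(unclass(empty) == 0L))

  expect_error(build_contingency(c("fortified"), c("fortified", "fortified")),
               "pair")
  expect_error(build_contingency("maybe", "fortified"), "Unknown class")
})

test_that("sensitivity and specificity follow the reporting conventions", {
  # expert-fortified row (242, 10, 1): procedure-ineligible excluded
  b12 <- matrix(c(242, 10, 1, 0, 220, 12, 9, 3, 3), 3, byrow = TRUE)
  expect_equal(sensitivity(b12), 242 / 252)
  expect_equal(sensitivity(b12, exclude_ineligible = FALSE), 242 / 253)
  # expert-non-fortified row (10, 357, 12): procedure-ineligible included
  ca <- matrix(c(101, 4, 1, 10, 357, 12, 12, 0, 3), 3, byrow = TRUE)
  expect_equal(specificity(ca), 357 / 379)
  expect_equal(specificity(ca, include_ineligible = FALSE), 357 / 367)

  zn <- matrix(c(91, 0, 0, 0, 381, 13, 12, 0, 3), 3, byrow = TRUE)
  expect_equal(sensitivity(zn), 1)
  degenerate <- matrix(c(0, 5, 0, 0, 5, 0, 0, 0, 0), 3, byrow = TRUE)
  expect_equal(sensitivity(degenerate), 0)
  expect_equal(specificity(degenerate), 1)
  none <- matrix(0, 3, 3)
  expect_error(sensitivity(none), "denominator")
  expect_error(specificity(none), "denominator")
})

test_that("Sison-Glaz intervals contain their estimates, live in [0,1], and sum sanely", {
  for (counts in list(c(101, 4, 1), c(10, 357, 12), c(12, 0, 3),
                      c(91, 0, 0), c(5, 3, 2), c(1, 1, 1, 1, 6))) {
    ci <- sison_glaz(counts)
    expect_true(all(ci$conf.low >= 0 & ci$conf.high <= 1))
    expect_true(all(ci$conf.low <= ci$estimate + 1e-12))
    expect_true(all(ci$estimate <= ci$conf.high + 1e-12))
    expect_equal(sum(ci$estimate), 1)
  }
  expect_error(sison_glaz(c(0, 0, 0)), "at least 1")
  expect_error(sison_glaz(c(-1, 2)), "non-negative")
  expect_error(sison_glaz(c(3, 2), alpha = 1.2), "alpha")
})

test_that("the coverage approximation tracks exact enumeration on small tables", {
  for (counts in list(c(5, 3, 2), c(10, 8, 2), c(15, 10, 5), c(20, 6, 4),
                      c(25, 3, 2))) {
    for (cc in 1:5) {
      approx <- fortiscan:::.sg_nu(cc, counts)
      exact <- exact_nu(cc, counts)
      expect_lt(abs(approx - exact), 0.04)
    }
  }
})

test_that("published interval fixtures reproduce (one-decimal percentages)", {
  pct <- function(x) round_half_up(100 * x, 1)

  ci <- sison_glaz(c(101, 4, 1))
  expect_equal(attr(ci, "c"), 3L)
  expect_equal(pct(ci$conf.low), c(92.5, 0.9, 0.0))
  expect_equal(pct(ci$conf.high)[2:3], c(7.7, 4.9))
  expect_lt(abs(pct(ci$conf.high)[1] - 99.2), 0.2)

  # a one-cell row degenerates gracefully to a zero-width interval at 1
  ci <- sison_glaz(c(91, 0, 0))
  expect_equal(ci$estimate, c(1, 0, 0))
  expect_equal(pct(ci$conf.low), c(100.0, 0.0, 0.0))
  expect_equal(pct(ci$conf.high), c(100.0, 1.8, 1.8))

  ci <- sison_glaz(c(242, 10, 1))
  expect_equal(pct(ci$conf.low), c(93.7, 2.0, 0.0))
  expect_equal(pct(ci$conf.high), c(98.1, 6.4, 2.9))

  ci <- sison_glaz(c(0, 381, 13))
  expect_equal(pct(ci$conf.low), c(0.0, 95.2, 1.8))
  expect_equal(pct(ci$conf.high), c(1.6, 98.3, 4.9))
})

test_that("Monte-Carlo simultaneous coverage is near nominal", {
  # moderately sized check here; the acceptance suite runs the full 5000
  withr::with_seed(1234, {
    p <- c(0.8, 0.15, 0.05)
    hits <- vapply(seq_len(500), function(i) {
      x <- as.vector(stats::rmultinom(1, 100, p))
      ci <- sison_glaz(x)
      all(p >= ci$conf.low - 1e-12 & p <= ci$conf.high + 1e-12)
    }, logical(1))
    expect_gte(mean(hits), 0.90)
  })
})

test_that("validation reports assemble tables, CIs, and headline rates", {
  corpus <- generate_corpus(synth_config(seed = 77))
  res <- classify_foods(corpus$records, trace = FALSE)
  report <- validate_classification(res, corpus$ground_truth)
  expect_s3_class(report, "validation_report")
  expect_setequal(names(report), unique(corpus$ground_truth$nutrient))

  td <- tidy(report)
  expect_true(all(c("nutrient", "expert_class", "procedure_class", "count",
                    "estimate", "conf.low", "conf.high") %in% names(td)))
  # row proportions sum to 1 within each (nutrient, expert class)
  sums <- dplyr::summarise(
    dplyr::group_by(td, nutrient, expert_class),
    s = sum(estimate), .groups = "drop"
  )
  expect_true(all(abs(sums$s - 1) < 1e-9))

  gl <- glance(report)
  expect_true(all(gl$sensitivity >= 0 & gl$sensitivity <= 1, na.rm = TRUE))
  expect_true(all(gl$agreement >= 0 & gl$agreement <= 1))

  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_csv(report, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(any(grepl("CI:", out$procedure_fortified)))

  # unpaired inputs are an error
  expect_error(validate_classification(res[-1, ], corpus$ground_truth),
               "unpaired")
})
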