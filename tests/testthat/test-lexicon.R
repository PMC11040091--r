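lex <- default_lexicon()
specs <- nutrient_specs()

test_that("specific terms match standalone, as compound leads, and behind prefixes", {
  zn <- spec_for("zinc")
  ca <- spec_for("calcium")

  m <- find_specific_terms("water, zinklactaat, aroma", zn, lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$term, "zinklactaat")

  m <- find_specific_terms("water, zink, aroma", zn, lex)
  expect_equal(m$term, "zink")

  # multiplier prefixes generalise the compound table
  m <- find_specific_terms("tricalciumcitraat, zout", ca, lex)
  expect_equal(nrow(m), 1)

  # multi-word terms match as consecutive tokens
  m <- find_specific_terms("calciumzouten van orthofosforzuur", ca, lex)
  expect_equal(m$term, "calciumzouten van orthofosforzuur")

  expect_equal(nrow(find_specific_terms("", zn, lex)), 0)
  expect_equal(nrow(find_specific_terms(NA_character_, zn, lex)), 0)
})

test_that("exclusion patterns cancel matches", {
  ca <- spec_for("calcium")
  expect_equal(nrow(find_specific_terms("calcium-D-pantothenaat", ca, lex)), 0)
  # the exclusion only removes the covered match, not others
  m <- find_specific_terms("calcium-d-pantothenaat, calciumcarbonaat", ca, lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$term, "calciumcarbonaat")
})

test_that("B-number codes match only standalone or glued to vitamine", {
  b12 <- spec_for("vitamin_b12")
  expect_equal(nrow(find_specific_terms("water, b12, suiker", b12, lex)), 1)
  expect_equal(nrow(find_specific_terms("vitamine-b12", b12, lex)), 1)
  expect_equal(nrow(find_specific_terms("vitamine b12", b12, lex)), 1)
  # bracketed corruption B(1)(2) is a data error and must not match
  expect_equal(nrow(find_specific_terms("vitamine b(1)(2)", b12, lex)), 0)
  # not as an arbitrary compound lead
  expect_equal(nrow(find_specific_terms("b129-zout", b12, lex)), 0)
})

test_that("every built-in term embedded once is found exactly once", {
  for (nu in specs$nutrient_id) {
    sp <- spec_for(nu)
    terms <- sp$specific_terms[[1]]
    text <- paste(terms, collapse = ", ")
    m <- find_specific_terms(text, sp, lex)
    expect_equal(nrow(m), length(terms))
    expect_setequal(m$term, terms)
  }
})

test_that("matching is case-insensitive and diacritics-insensitive", {
  ca <- spec_for("calcium")
  base <- "zout, CALCIUMCARBONAAT, stabilisator (E410)"
  ref <- find_specific_terms(base, ca, lex)
  for (s in 1:20) {
    m <- find_specific_terms(flip_case(base, s), ca, lex)
    expect_equal(m$term, ref$term)
    expect_equal(m$start, ref$start)
  }
  expect_equal(find_specific_terms("calciëm", ca, lex)$term, character(0))
})

test_that("generic wordings match only when not qualified by a nutrient name", {
  g <- find_generic_terms("met toegevoegde vitaminen en mineralen", lex, specs)
  expect_equal(nrow(g), 1)
  expect_equal(g$term, "vitaminen en mineralen")

  expect_equal(nrow(find_generic_terms("vitamine C", lex, specs)), 0)
  expect_equal(nrow(find_generic_terms("vitamine b12", lex, specs)), 0)
  expect_equal(nrow(find_generic_terms("bloem, suiker", lex, specs)), 0)
  # an ingredient separator breaks the qualification
  expect_equal(nrow(find_generic_terms("vitaminen, calcium", lex, specs)), 2 - 1)
  # compound tokens do not trigger generic words ("mineraalwater")
  expect_equal(nrow(find_generic_terms("natuurlijk mineraalwater", lex, specs)), 0)
})

test_that("additive context needs a class name governing the match", {
  ca <- spec_for("calcium")
  zn <- spec_for("zinc")

  m <- find_specific_terms("verdikkingsmiddel (calciumalginaat)", ca, lex)
  expect_true(m$in_additive_context)

  m <- find_specific_terms("antioxidant: zinkgluconaat", zn, lex)
  expect_true(m$in_additive_context)

  m <- find_specific_terms("calciumcarbonaat, zout", ca, lex)
  expect_false(m$in_additive_context)

  # a comma between class and nutrient breaks the government
  m <- find_specific_terms("stabilisator (e410), calciumcarbonaat", ca, lex)
  expect_false(m$in_additive_context)

  # colon group extends to the ingredient separator, not past it
  m <- find_specific_terms("stabilisator: guarpitmeel, calciumcarbonaat", ca, lex)
  expect_false(m$in_additive_context)

  expect_true(detect_additive_context(
    "verdikkingsmiddel (calciumalginaat)",
    find_specific_terms("verdikkingsmiddel (calciumalginaat)", ca, lex)[1, ],
    lex
  ))
})

test_that("remark phrases flag natural content and fortification wording", {
  ca <- spec_for("calcium")
  fa <- spec_for("folic_acid")

  m <- find_specific_terms("rijk aan calcium", ca, lex)
  expect_true(m$in_natural_content_remark)
  expect_false(m$in_fortification_remark)

  m <- find_specific_terms("verrijkt met foliumzuur", fa, lex)
  expect_true(m$in_fortification_remark)
  expect_false(m$in_natural_content_remark)

  m <- find_specific_terms("calcium", ca, lex)
  expect_false(m$in_natural_content_remark)
  expect_false(m$in_fortification_remark)

  fl <- detect_remarks("rijk aan calcium",
                       find_specific_terms("rijk aan calcium", ca, lex)[1, ], lex)
  expect_true(fl[["in_natural_content_remark"]])

  # outside the 3-token window the phrase no longer governs
  far <- "rijk aan suiker zout aroma calcium"
  m <- find_specific_terms(far, ca, lex)
  expect_false(m$in_natural_content_remark)
})

test_that("matching is deterministic and span offsets index the normalised text", {
  zn <- spec_for("zinc")
  text <- "Water, Zinklactaat (12%), aroma"
  m1 <- find_specific_terms(text, zn, lex)
  m2 <- find_specific_terms(text, zn, lex)
  expect_identical(m1, m2)
  norm <- normalize_label_text(text)
  expect_equal(substr(norm, m1$start + 1, m1$end), "zinklactaat")
})

test_that("the default lexicon carries the 24 functional ingredient classes", {
  expect_equal(nrow(lex$additive_classes), 24)
  expect_true(all(c("stabilisator", "antioxidant", "verdikkingsmiddel",
                    "gemodificeerd zetmeel") %in% lex$additive_classes$dutch))
})
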