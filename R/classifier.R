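# The seven-step decision tree.
#
# Per nutrient, each food is routed as follows:
#   1  ineligible food group (or none)        -> ineligible
#   2  no declared nutrient value             -> step 7
#   3  declared value not significant         -> step 7
#   4  no specific search term in ingredients -> step 5, else step 6
#   5  generic vitamin/mineral wording        -> fortified, else step 7
#   6  all matches in additive context        -> step 7
#      natural-content remark (and no plain fortificant match) -> non-fortified
#      otherwise                              -> fortified
#   7  term + "added/fortified" wording in legal name or mandatory
#      particulars -> fortified; term + "source of/rich in" -> non-fortified;
#      anything else -> non-fortified (natural amounts)
#
# Missing text fields are treated as empty at steps 4-7; missing nutrient
# values are *not* zero (absence routes 2 -> 7, an explicit 0 routes 3 -> 7).

.labels <- c("fortified", "non_fortified", "ineligible")

# effective declared value for a nutrient; folic acid folds the two label
# columns into one indicator: dietary folate equivalents win when present
effective_value <- function(records, nutrient) {
  records <- as_tibble(records)
  n <- nrow(records)
  get <- function(col) {
    if (col %in% names(records)) as.numeric(records[[col]]) else rep(NA_real_, n)
  }
  if (nutrient == "folic_acid") {
    dfe <- get("dfe")
    fa <- get("folic_acid")
    if_else(!is.na(dfe), dfe, fa)
  } else {
    get(nutrient)
  }
}

# raw (deduplicated, exclusion-filtered) specific-term match positions for
# one nutrient, as an integer matrix -- flag computation happens without
# building tibbles, which matters on database-scale corpora
.match_positions <- function(tok, spec, lexicon) {
  m <- .match_terms(tok, spec$specific_terms, lexicon$prefixes)
  if (nrow(m) > 0 && length(spec$exclusion_patterns) > 0) {
    covering <- tok$token[m[, "first"]]
    excluded <- rep(FALSE, nrow(m))
    for (pat in spec$exclusion_patterns) {
      excluded <- excluded | stringr::str_detect(covering, stringr::fixed(pat))
    }
    m <- m[!excluded, , drop = FALSE]
  }
  .dedup_matches(m, tok, nchar(spec$specific_terms))
}

# generic-wording match positions after the qualification check
.generic_positions <- function(tok, lexicon, qualifier_set) {
  phrases <- lexicon$generic_terms
  k_len <- vapply(strsplit(phrases, " +"), length, 0L)
  out <- vector("list", length(phrases))
  for (pi in order(-k_len)) {
    parts <- strsplit(phrases[pi], " +")[[1]]
    if (length(parts) == 1) {
      first <- which(tok$token == parts)
      mm <- cbind(first = first, last = first)
    } else {
      mm <- match_token_phrase(tok, parts)
    }
    if (nrow(mm)) out[[pi]] <- cbind(mm, term = pi)
  }
  m <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(m) || nrow(m) == 0) {
    return(cbind(first = integer(0), last = integer(0), term = integer(0)))
  }
  m <- .dedup_matches(m, tok)
  n <- length(tok$token)
  qualified <- vapply(seq_len(nrow(m)), function(i) {
    nxt <- m[i, "last"] + 1L
    nxt <= n && !tok$hard_before[nxt] && .is_qualifier(tok$token[nxt], qualifier_set)
  }, logical(1))
  m[!qualified, , drop = FALSE]
}

# per-unique-text ingredient-list analysis
.analyze_ingredients <- function(texts, specs, lexicon) {
  qs <- .build_qualifier_set(lexicon, specs)
  nn <- nrow(specs)
  nt <- length(texts)
  has_term <- all_additive <- any_plain <- any_natural <-
    matrix(FALSE, nt, nn, dimnames = list(NULL, specs$nutrient_id))
  has_generic <- rep(FALSE, nt)
  spec_list <- lapply(seq_len(nn), function(i) as_nutrient_spec(specs[i, ]))
  for (t in seq_len(nt)) {
    tok <- tokenize_label(texts[t])
    if (is.null(tok)) next
    has_generic[t] <- nrow(.generic_positions(tok, lexicon, qs)) > 0
    ctx <- NULL  # anchors/phrase ends computed once per text, lazily
    for (i in seq_len(nn)) {
      m <- .match_positions(tok, spec_list[[i]], lexicon)
      if (nrow(m) == 0) next
      if (is.null(ctx)) {
        ctx <- list(
          anchors = .additive_anchor_tokens(tok, lexicon),
          nat = .phrase_ends(tok, lexicon$natural_content_phrases)
        )
      }
      additive <- vapply(m[, "first"], .in_additive_context, logical(1),
                         tok = tok, anchors = ctx$anchors,
                         window = lexicon$additive_window)
      natural <- vapply(m[, "first"], function(j) {
        any(ctx$nat < j & ctx$nat >= j - lexicon$remark_window)
      }, logical(1))
      has_term[t, i] <- TRUE
      all_additive[t, i] <- all(additive)
      any_plain[t, i] <- any(!additive & !natural)
      any_natural[t, i] <- any(!additive & natural)
    }
  }
  list(has_term = has_term, all_additive = all_additive,
       any_plain = any_plain, any_natural = any_natural,
       has_generic = has_generic)
}

# per-unique-text step-7 analysis of a label-claim field: does it carry a
# (specific or generic) term under fortification / natural-content wording?
.analyze_claims <- function(texts, specs, lexicon) {
  qs <- .build_qualifier_set(lexicon, specs)
  nn <- nrow(specs)
  nt <- length(texts)
  fort <- natural <- matrix(FALSE, nt, nn, dimnames = list(NULL, specs$nutrient_id))
  spec_list <- lapply(seq_len(nn), function(i) as_nutrient_spec(specs[i, ]))
  w <- NULL
  for (t in seq_len(nt)) {
    tok <- tokenize_label(texts[t])
    if (is.null(tok)) next
    nat_ends <- .phrase_ends(tok, lexicon$natural_content_phrases)
    fort_ends <- .phrase_ends(tok, lexicon$fortification_phrases)
    w <- lexicon$remark_window
    flag_of <- function(m) {
      if (nrow(m) == 0) return(c(FALSE, FALSE))
      f <- vapply(m[, "first"], function(j) any(fort_ends < j & fort_ends >= j - w),
                  logical(1))
      nl <- vapply(m[, "first"], function(j) any(nat_ends < j & nat_ends >= j - w),
                   logical(1))
      c(any(f), any(nl))
    }
    g <- flag_of(.generic_positions(tok, lexicon, qs))
    for (i in seq_len(nn)) {
      s <- flag_of(.match_positions(tok, spec_list[[i]], lexicon))
      fort[t, i] <- g[1] || s[1]
      natural[t, i] <- g[2] || s[2]
    }
  }
  list(fort = fort, natural = natural)
}

#' Step 1: is the food eligible?
#'
#' Nutrient-independent: a food is ineligible when its food group is one of
#' the ineligible groups (infant foods, medical foods, total diet
#' replacement, supplements) or missing.
#'
#' @param records A data frame of branded-food records.
#' @param rule An [eligibility_rule()].
#' @return Character vector, `"eligible"` or `"ineligible"`.
#' @export
step1_eligible <- function(records, rule = eligibility_rule()) {
  records <- as_tibble(records)
  grp <- if ("food_group" %in% names(records)) {
    as.character(records$food_group)
  } else {
    rep(NA_character_, nrow(records))
  }
  grp_norm <- normalize_label_text(grp)
  missing_grp <- is.na(grp) | !nzchar(trimws(grp))
  inel <- (missing_grp & rule$treat_unclassified_as_ineligible) |
    (!missing_grp & grp_norm %in% rule$ineligible_groups)
  if_else(inel, "ineligible", "eligible")
}

#' Step 2: is a nutrient value declared?
#' @inheritParams step1_eligible
#' @param nutrient A nutrient identifier.
#' @return Character vector, `"to_step3"` or `"to_step7"`.
#' @export
step2_value_declared <- function(records, nutrient) {
  if_else(!is.na(effective_value(records, nutrient)), "to_step3", "to_step7")
}

#' Step 3: is the declared value significant?
#' @inheritParams step2_value_declared
#' @param specs A [nutrient_specs()] tibble containing `nutrient`.
#' @param beverage A [beverage_rule()].
#' @return Character vector, `"to_step4"` or `"to_step7"`.
#' @export
step3_significant <- function(records, nutrient, specs = nutrient_specs(),
                              beverage = beverage_rule()) {
  spec <- specs[specs$nutrient_id == nutrient, ]
  v <- effective_value(records, nutrient)
  sig <- is_significant(v, spec, is_beverage(records, beverage))
  if_else(!is.na(sig) & sig, "to_step4", "to_step7")
}

#' Step 4: is a specific search term in the ingredient list?
#' @inheritParams step3_significant
#' @param lexicon A [default_lexicon()].
#' @return Character vector, `"to_step6"` or `"to_step5"`.
#' @export
step4_term_in_ingredients <- function(records, nutrient,
                                      specs = nutrient_specs(),
                                      lexicon = default_lexicon()) {
  spec <- as_nutrient_spec(specs[specs$nutrient_id == nutrient, ])
  found <- vapply(.ingredient_texts(records), function(txt) {
    nrow(.find_specific_tok(tokenize_label(txt), spec, lexicon)) > 0
  }, logical(1))
  if_else(found, "to_step6", "to_step5")
}

#' Step 5: generic vitamin/mineral wording in the ingredient list?
#' @inheritParams step4_term_in_ingredients
#' @return Character vector, `"fortified"` or `"to_step7"`.
#' @export
step5_generic_terms <- function(records, nutrient, specs = nutrient_specs(),
                                lexicon = default_lexicon()) {
  qs <- .build_qualifier_set(lexicon, specs)
  found <- vapply(.ingredient_texts(records), function(txt) {
    nrow(.find_generic_tok(tokenize_label(txt), lexicon, qs)) > 0
  }, logical(1))
  if_else(found, "fortified", "to_step7")
}

#' Step 6: food additive or naturally present?
#' @inheritParams step4_term_in_ingredients
#' @return Character vector: `"to_step7"` (all matches in additive context),
#'   `"non_fortified"` (natural-content remark, no plain fortificant match),
#'   or `"fortified"`.
#' @export
step6_additive_or_natural <- function(records, nutrient,
                                      specs = nutrient_specs(),
                                      lexicon = default_lexicon()) {
  spec <- as_nutrient_spec(specs[specs$nutrient_id == nutrient, ])
  vapply(.ingredient_texts(records), function(txt) {
    m <- .find_specific_tok(tokenize_label(txt), spec, lexicon)
    if (nrow(m) == 0) {
      abort("step 6 requires at least one specific term match (step 4)")
    }
    if (all(m$in_additive_context)) return("to_step7")
    if (any(!m$in_additive_context & !m$in_natural_content_remark)) {
      return("fortified")
    }
    "non_fortified"
  }, character(1), USE.NAMES = FALSE)
}

#' Step 7: additional wording on the label?
#'
#' Searches the legal name and the mandatory particulars (and the food name
#' when `config$search_food_name` is set) for specific or generic terms. A
#' term under "added / fortified with" wording classifies fortified; under
#' "source of / rich in" wording, non-fortified; no wording at all means the
#' declared amounts are natural and the food is non-fortified. A phrase
#' without any term never classifies fortified.
#'
#' @inheritParams step2_value_declared
#' @param config A [fortification_config()].
#' @return Character vector, `"fortified"` or `"non_fortified"`.
#' @export
step7_label_text <- function(records, nutrient,
                             config = fortification_config()) {
  records <- as_tibble(records)
  fields <- c("legal_name", "mandatory_particulars",
              if (config$search_food_name) "food_name")
  n <- nrow(records)
  fort <- natural <- rep(FALSE, n)
  for (f in fields) {
    txts <- if (f %in% names(records)) as.character(records[[f]]) else rep(NA_character_, n)
    u <- unique(txts)
    fl <- .analyze_claims(u, config$specs, config$lexicon)
    i <- match(txts, u)
    fort <- fort | fl$fort[i, nutrient]
    natural <- natural | fl$natural[i, nutrient]
  }
  case_when(fort ~ "fortified",
            natural ~ "non_fortified",
            TRUE ~ "non_fortified")
}

.ingredient_texts <- function(records) {
  records <- as_tibble(records)
  if ("ingredient_list" %in% names(records)) {
    as.character(records$ingredient_list)
  } else {
    rep(NA_character_, nrow(records))
  }
}

.step_outcomes <- list(
  `1` = c(y = "eligible", n = "ineligible"),
  `2` = c(y = "value_declared", n = "value_missing"),
  `3` = c(y = "significant", n = "not_significant"),
  `4` = c(y = "term_found", n = "no_term"),
  `5` = c(y = "generic_found", n = "no_generic"),
  `6` = c(additive = "additive_context", natural = "natural_content",
          plain = "fortificant"),
  `7` = c(fort = "fortified_wording", natural = "natural_wording",
          none = "no_wording")
)

#' Classify foods as fortified, non-fortified, or ineligible
#'
#' Runs the seven-step decision tree for every record and every configured
#' nutrient. Deterministic; degraded data (missing fields) is routed, never
#' an error.
#'
#' @param records A data frame with columns `food_id` (unique) and any of
#'   `food_group`, `food_subgroup`, `food_name`, `ingredient_list`,
#'   `legal_name`, `mandatory_particulars`, `calcium` (mg), `folic_acid`
#'   (ug), `dfe` (ug), `vitamin_b12` (ug), `zinc` (mg), `single_portion`.
#'   Nutrient values are amounts per 100 g / 100 mL; `NA` means "not
#'   declared" (distinct from an explicit 0). `single_portion` is carried
#'   but ignored: the tree does not differentiate single-portion foods.
#' @param config A [fortification_config()].
#' @param nutrients Nutrients to classify; defaults to all configured.
#' @param trace Keep the per-classification step trace as a list column?
#' @return A tibble of class `fortification_results` with one row per
#'   (food, nutrient): `food_id`, `nutrient`, `label`, `terminal_step`,
#'   `reason`, step outcome columns `step1`..`step7` (`"y"`/`"n"`/`"-"`),
#'   and (when `trace = TRUE`) a `trace` list column replayable with
#'   [replay_trace()].
#' @examples
#' rec <- tibble::tibble(
#'   food_id = "f1", food_group = "Drinks",
#'   ingredient_list = "water, suiker, vitamine b12", vitamin_b12 = 0.25
#' )
#' classify_foods(rec, nutrients = "vitamin_b12")
#' @export
classify_foods <- function(records, config = fortification_config(),
                           nutrients = config$specs$nutrient_id,
                           trace = TRUE) {
  records <- as_tibble(records)
  if (!"food_id" %in% names(records)) abort("`records` needs a `food_id` column")
  ids <- as.character(records$food_id)
  if (anyDuplicated(ids)) abort("`food_id` must be unique within a dataset")
  specs <- config$specs[config$specs$nutrient_id %in% nutrients, ]
  if (nrow(specs) < length(nutrients)) {
    abort(paste0("Nutrient(s) not in configuration: ",
                 paste(setdiff(nutrients, specs$nutrient_id), collapse = ", ")))
  }

  n <- nrow(records)
  eligible <- step1_eligible(records, config$eligibility) == "eligible"
  bev <- is_beverage(records, config$beverage)

  ing <- .ingredient_texts(records)
  u_ing <- unique(ing)
  ingf <- .analyze_ingredients(u_ing, specs, config$lexicon)
  ii <- match(ing, u_ing)

  claim_fields <- c("legal_name", "mandatory_particulars",
                    if (config$search_food_name) "food_name")
  fort_claim <- natural_claim <-
    matrix(FALSE, n, nrow(specs), dimnames = list(NULL, specs$nutrient_id))
  for (f in claim_fields) {
    txts <- if (f %in% names(records)) as.character(records[[f]]) else rep(NA_character_, n)
    u <- unique(txts)
    fl <- .analyze_claims(u, specs, config$lexicon)
    i <- match(txts, u)
    fort_claim <- fort_claim | fl$fort[i, , drop = FALSE]
    natural_claim <- natural_claim | fl$natural[i, , drop = FALSE]
  }

  out <- vector("list", nrow(specs))
  for (s in seq_len(nrow(specs))) {
    nut <- specs$nutrient_id[s]
    spec <- specs[s, ]
    value <- effective_value(records, nut)
    declared <- !is.na(value)
    signif <- declared & value >= significance_threshold(spec, bev)
    has_term <- ingf$has_term[ii, s]
    all_add <- ingf$all_additive[ii, s]
    any_plain <- ingf$any_plain[ii, s]
    has_gen <- ingf$has_generic[ii]
    fclaim <- fort_claim[, s]
    nclaim <- natural_claim[, s]

    o <- matrix(NA_character_, n, 7)
    o[, 1] <- if_else(eligible, "y", "n")
    vis2 <- eligible
    o[vis2, 2] <- if_else(declared[vis2], "y", "n")
    vis3 <- vis2 & declared
    o[vis3, 3] <- if_else(signif[vis3], "y", "n")
    vis4 <- vis3 & signif
    o[vis4, 4] <- if_else(has_term[vis4], "y", "n")
    vis5 <- vis4 & !has_term
    o[vis5, 5] <- if_else(has_gen[vis5], "y", "n")
    vis6 <- vis4 & has_term
    o[vis6, 6] <- case_when(
      all_add[vis6] ~ "y",
      any_plain[vis6] ~ "n",
      TRUE ~ "y"
    )
    # step 6 detail for routing: additive -> step 7, natural -> terminal
    six_kind <- rep(NA_character_, n)
    six_kind[vis6] <- case_when(
      all_add[vis6] ~ "additive",
      any_plain[vis6] ~ "plain",
      TRUE ~ "natural"
    )
    vis7 <- (vis2 & !declared) | (vis3 & !signif) | (vis5 & !has_gen) |
      (vis6 & six_kind == "additive")
    o[vis7, 7] <- if_else(fclaim[vis7], "y", "n")
    seven_kind <- rep(NA_character_, n)
    seven_kind[vis7] <- case_when(
      fclaim[vis7] ~ "fort",
      nclaim[vis7] ~ "natural",
      TRUE ~ "none"
    )

    label <- case_when(
      !eligible ~ "ineligible",
      vis5 & has_gen ~ "fortified",
      six_kind == "plain" ~ "fortified",
      six_kind == "natural" ~ "non_fortified",
      seven_kind == "fort" ~ "fortified",
      vis7 ~ "non_fortified"
    )
    terminal <- case_when(
      !eligible ~ 1L,
      vis5 & has_gen ~ 5L,
      six_kind %in% c("plain", "natural") ~ 6L,
      TRUE ~ 7L
    )
    reason <- case_when(
      !eligible ~ "step1_ineligible",
      vis5 & has_gen ~ "step5_generic",
      six_kind == "plain" ~ "step6_fortificant",
      six_kind == "natural" ~ "step6_natural",
      seven_kind == "fort" ~ "step7_fortified_wording",
      seven_kind == "natural" ~ "step7_natural_wording",
      TRUE ~ "step7_natural_default"
    )

    res <- tibble(
      food_id = ids, nutrient = nut,
      label = factor(label, levels = .labels),
      terminal_step = terminal, reason = reason,
      step1 = o[, 1], step2 = o[, 2], step3 = o[, 3], step4 = o[, 4],
      step5 = o[, 5], step6 = o[, 6], step7 = o[, 7]
    )
    if (trace) {
      det <- o
      det[vis6, 6] <- unname(.step_outcomes[["6"]][six_kind[vis6]])
      det[vis7, 7] <- unname(.step_outcomes[["7"]][seven_kind[vis7]])
      for (st in c(1:5)) {
        v <- !is.na(det[, st])
        det[v, st] <- unname(.step_outcomes[[st]][det[v, st]])
      }
      res$trace <- lapply(seq_len(n), function(i) {
        steps <- which(!is.na(det[i, ]))
        list(step = steps, outcome = unname(det[i, steps]))
      })
    }
    out[[s]] <- res
  }
  res <- bind_rows(out)
  res <- res[order(match(res$food_id, ids)), ]
  class(res) <- c("fortification_results", class(res))
  res
}

.step_cols <- function(x) {
  for (st in 1:7) {
    cn <- paste0("step", st)
    if (!cn %in% names(x)) abort("results are missing the step outcome columns")
  }
  invisible(x)
}

#' Per-step yes/no tally
#'
#' For each nutrient, counts how many foods answered each decision-tree step
#' with "yes", plus the final label counts. The tree's bookkeeping identity
#' `fortified = yes4 - yes6 + yes5 + yes7` holds on every tally: foods with
#' a fortificant term (yes4) minus those diverted as additive/natural at
#' step 6 (yes6), plus generic-wording classifications at step 5 (yes5) and
#' label-wording classifications at step 7 (yes7). When no food is
#' classified at step 5 this reduces to `fortified = yes4 - yes6 + yes7`.
#'
#' @param results A `fortification_results` tibble from [classify_foods()].
#' @return A tibble with one row per nutrient: `n`, `yes1`..`yes7`,
#'   `fortified`, `non_fortified`, `ineligible`, and `identity_ok`.
#' @export
step_tally <- function(results) {
  .step_cols(results)
  results %>%
    group_by(nutrient = .data$nutrient) %>%
    summarise(
      n = n(),
      yes1 = sum(.data$step1 == "y", na.rm = TRUE),
      yes2 = sum(.data$step2 == "y", na.rm = TRUE),
      yes3 = sum(.data$step3 == "y", na.rm = TRUE),
      yes4 = sum(.data$step4 == "y", na.rm = TRUE),
      yes5 = sum(.data$step5 == "y", na.rm = TRUE),
      yes6 = sum(.data$step6 == "y", na.rm = TRUE),
      yes7 = sum(.data$step7 == "y", na.rm = TRUE),
      fortified = sum(.data$label == "fortified"),
      non_fortified = sum(.data$label == "non_fortified"),
      ineligible = sum(.data$label == "ineligible"),
      .groups = "drop"
    ) %>%
    mutate(identity_ok = .data$fortified ==
             .data$yes4 - .data$yes6 + .data$yes5 + .data$yes7)
}

#' Replay a classification trace
#'
#' Walks the recorded step outcomes and returns the label they imply;
#' errors if the trace is not a valid path through the tree (must start at
#' step 1, step numbers strictly increasing, terminal outcome conclusive).
#'
#' @param trace One element of the `trace` column of [classify_foods()]
#'   output: a list with integer vector `step` and character `outcome`.
#' @return `"fortified"`, `"non_fortified"`, or `"ineligible"`.
#' @export
replay_trace <- function(trace) {
  steps <- trace$step
  out <- trace$outcome
  if (length(steps) == 0 || steps[1] != 1L) abort("trace must start at step 1")
  if (any(diff(steps) <= 0)) abort("trace steps must strictly increase")
  expected <- 1L
  for (i in seq_along(steps)) {
    if (steps[i] != expected) abort("trace skips a step its routing requires")
    expected <- switch(
      paste0(steps[i], ":", out[i]),
      "1:eligible" = 2L, "1:ineligible" = return("ineligible"),
      "2:value_declared" = 3L, "2:value_missing" = 7L,
      "3:significant" = 4L, "3:not_significant" = 7L,
      "4:term_found" = 6L, "4:no_term" = 5L,
      "5:generic_found" = return("fortified"), "5:no_generic" = 7L,
      "6:fortificant" = return("fortified"),
      "6:natural_content" = return("non_fortified"),
      "6:additive_context" = 7L,
      "7:fortified_wording" = return("fortified"),
      "7:natural_wording" = return("non_fortified"),
      "7:no_wording" = return("non_fortified"),
      abort(paste0("unknown trace outcome at step ", steps[i]))
    )
  }
  abort("trace ends without a terminal outcome")
}
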