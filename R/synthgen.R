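# Seeded generator of branded-food-database-shaped synthetic corpora.
#
# The restricted national database cannot ship with the package, so every
# classifier branch and every documented error mode is exercised on
# generated Dutch label data instead. Each scenario family constructs label
# text whose route through the decision tree is known at build time, and
# the generator records two labels per (food, nutrient): `truth`, what a
# legally literate reader would conclude from the label, and `expected`,
# what the decision tree must return. The two differ by design for the
# documented error modes (mineral-water calcium, below-significance
# declarations, mis-filed ineligible foods, corrupted records).
#
# Scenario families:
#   clean_fortified     fortificant term in the list + significant value
#   generic_fortified   >= 3 nutrients added, written as generic wording
#   additive_decoy      nutrient compound governed by an additive class
#   natural_decoy       "rijk aan / bron van" remark, natural content
#   mineral_water       natural calcium spelled out in the list (procedure
#                       false positive, reproduced on purpose)
#   below_significance  fortificant declared below the cutoff (procedure
#                       false negative vs the reader)
#   label_fortified     value missing, "verrijkt met ..." in the legal name
#   ineligible          correctly filed ineligible foods
#   misfiled_ineligible ineligible foods filed into an eligible group
#   missing_group       no food-group classification (procedure ineligible,
#                       reader can still judge)
#   truncated           ingredient list cut off inside the fortificant term
#   value_error         plain food with a 1000x unit/decimal error
#   filler              plain non-fortified foods
#   typo (knob)         clean fortified with a corrupted term spelling

.synth_templates <- function() {
  path <- system.file("extdata", "synth-templates.yaml", package = "fortiscan")
  yaml::read_yaml(path)
}

.scenario_names <- c(
  "clean_fortified", "generic_fortified", "additive_decoy", "natural_decoy",
  "mineral_water", "below_significance", "label_fortified", "ineligible",
  "misfiled_ineligible", "missing_group", "truncated", "value_error",
  "filler"
)

#' Scenario configuration for the synthetic generator
#'
#' Counts are foods per scenario family. The default mirrors the
#' validation-study design: roughly 100 procedure-fortified foods per
#' nutrient (mostly clean, some generic-wording and label-wording cases)
#' plus a sample of decoys, error modes, and plain foods.
#'
#' @param n Named integer vector or list overriding scenario counts; see
#'   the package vignette for the families.
#' @param nutrients Nutrient identifiers to target (cycled over fortified
#'   scenarios).
#' @param typo_prob Probability that a clean fortified record gets a
#'   spelling error inside its fortificant term (making it ground-truth
#'   fortified but expected-procedure non-fortified).
#' @param seed Integer random seed; a fixed seed makes the corpus
#'   byte-identical across runs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = NULL,
                         nutrients = c("calcium", "folic_acid",
                                       "vitamin_b12", "zinc"),
                         typo_prob = 0, seed = 1L) {
  counts <- c(
    clean_fortified = 280L, generic_fortified = 16L, additive_decoy = 30L,
    natural_decoy = 20L, mineral_water = 10L, below_significance = 10L,
    label_fortified = 40L, ineligible = 6L, misfiled_ineligible = 12L,
    missing_group = 13L, truncated = 8L, value_error = 5L, filler = 60L
  )
  if (!is.null(n)) {
    n <- unlist(n)
    bad <- setdiff(names(n), .scenario_names)
    if (length(bad) > 0) {
      abort(paste0("Unknown scenario(s): ", paste(bad, collapse = ", ")))
    }
    counts[] <- 0L
    counts[names(n)] <- as.integer(n)
  }
  if (any(counts < 0)) abort("scenario counts must be non-negative")
  if (sum(counts) < 1) abort("infeasible config: no records requested")
  if (!(typo_prob >= 0 && typo_prob <= 1)) abort("`typo_prob` must be in [0, 1]")
  structure(
    list(counts = counts, nutrients = nutrients,
         typo_prob = typo_prob, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Validation-design configuration
#'
#' The scenario mix emulating the validation study: for each nutrient about
#' 100 foods the procedure classifies as fortified, plus a sample of other
#' foods (decoys, error modes, ineligible and plain foods).
#'
#' @inheritParams synth_config
#' @return A `synth_config`.
#' @export
validation_design_config <- function(seed = 1L) {
  synth_config(seed = seed)
}

# threshold lookup consistent with the default beverage rule
.applicable_threshold <- function(spec, beverage) {
  if (beverage) spec$beverage_threshold else spec$solid_threshold
}

# swap the 2nd and 3rd characters of the first word of a term: breaks the
# leading-component match for every built-in term without creating another
.typo_term <- function(term) {
  ch <- strsplit(term, "")[[1]]
  if (length(ch) < 3) return(paste0(rev(ch), collapse = ""))
  tmp <- ch[2]; ch[2] <- ch[3]; ch[3] <- tmp
  paste(ch, collapse = "")
}

#' Generate a synthetic branded-food corpus with ground truth
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_corpus` with elements `records` (a tibble
#'   in the [classify_foods()] column contract) and `ground_truth` (a tibble
#'   with `food_id`, `nutrient`, `truth`, `expected`, `scenario`,
#'   `compliant`). `truth` is the label a legally literate reader would
#'   assign from the label; `expected` is the label the decision tree is
#'   designed to assign. Fixed seed implies identical output.
#' @examples
#' corpus <- generate_corpus(synth_config(n = c(clean_fortified = 5), seed = 7))
#' corpus$records$ingredient_list[1]
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  tpl <- .synth_templates()
  specs <- nutrient_specs()
  all_nut <- specs$nutrient_id
  target_pool <- config$nutrients

  withr::with_seed(config$seed, {
    recs <- list()
    gts <- list()
    idx <- 0L

    eligible_groups <- setdiff(food_groups(), "Miscellaneous")
    ineligible_groups_ <- c(
      "Foods and formulae for infants and young children",
      "Foods for specific medical purposes",
      "Total diet replacement for weight control", "Food supplements"
    )

    base_list <- function(k = NULL) {
      k <- k %||% sample(3:6, 1)
      parts <- sample(tpl$base_ingredients, k)
      if (runif(1) < 0.3) {
        parts <- append(parts, sample(tpl$harmless_additive_fragments, 1),
                        after = sample(seq_along(parts), 1))
      }
      parts
    }
    food_name <- function() {
      paste(sample(tpl$food_name_stems, 1), sample(tpl$brand_suffixes, 1))
    }
    pick_group <- function(beverage_share = 0.25) {
      if (runif(1) < beverage_share) {
        if (runif(1) < 0.7) {
          list(group = "Drinks", subgroup = NA_character_)
        } else {
          list(group = "Milk, milk products, and milk replacers",
               subgroup = "dairy drinks")
        }
      } else {
        list(group = sample(setdiff(eligible_groups, "Drinks"), 1),
             subgroup = NA_character_)
      }
    }
    is_bev <- function(g) {
      identical(g$group, "Drinks") ||
        (!is.na(g$subgroup) && g$subgroup %in% c("dairy drinks"))
    }
    spec_of <- function(nut) specs[specs$nutrient_id == nut, ]

    emit <- function(scenario, group, subgroup, name, ingredients,
                     legal_name = NA_character_, particulars = NA_character_,
                     values = list(), truth, expected, compliant) {
      idx <<- idx + 1L
      id <- sprintf("F%05d", idx)
      recs[[idx]] <<- list(
        food_id = id, food_group = group, food_subgroup = subgroup,
        food_name = name,
        ingredient_list = if (is.na(ingredients) || !nzchar(ingredients)) {
          NA_character_
        } else ingredients,
        legal_name = legal_name, mandatory_particulars = particulars,
        calcium = values$calcium %||% NA_real_,
        folic_acid = values$folic_acid %||% NA_real_,
        dfe = values$dfe %||% NA_real_,
        vitamin_b12 = values$vitamin_b12 %||% NA_real_,
        zinc = values$zinc %||% NA_real_,
        single_portion = runif(1) < 0.05
      )
      gts[[idx]] <<- list(
        food_id = id, truth = unname(truth[all_nut]),
        expected = unname(expected[all_nut]),
        scenario = scenario, compliant = compliant
      )
    }

    base_labels <- function(value) setNames(rep(value, length(all_nut)), all_nut)

    nut_cycle <- rep(target_pool, length.out = max(1, sum(config$counts)))
    cyc_i <- 0L
    next_nut <- function() {
      cyc_i <<- cyc_i + 1L
      nut_cycle[(cyc_i - 1L) %% length(nut_cycle) + 1L]
    }

    # -- clean fortified (with optional typo corruption) ------------------
    for (r in seq_len(config$counts["clean_fortified"])) {
      nut <- next_nut()
      g <- pick_group()
      sp <- spec_of(nut)
      thr <- .applicable_threshold(sp, is_bev(g))
      value <- round(thr * runif(1, 1.0, 2.0), 4)
      typo <- runif(1) < config$typo_prob
      forms <- tpl$fortificant_forms[[nut]]
      # typos only corrupt single-word forms, so the damaged token cannot
      # leave a matchable residue ("vitamine b21" would still carry a bare
      # generic "vitamine")
      if (typo) forms <- forms[grepl("^[a-z0-9]+$", forms)]
      form <- sample(forms, 1)
      written <- if (typo) .typo_term(form) else form
      parts <- base_list()
      parts <- append(parts, written, after = sample(seq_along(parts), 1))
      truth <- base_labels("non_fortified"); truth[nut] <- "fortified"
      expected <- base_labels("non_fortified")
      expected[nut] <- if (typo) "non_fortified" else "fortified"
      vals <- list()
      # folate producers declare either folic acid or dietary folate
      # equivalents; the classifier folds both into one indicator
      col <- if (nut == "folic_acid" && runif(1) < 0.5) "dfe" else nut
      vals[[col]] <- value
      emit(if (typo) "typo" else "clean_fortified", g$group, g$subgroup,
           food_name(), paste(parts, collapse = ", "),
           values = vals, truth = truth, expected = expected,
           compliant = !typo)
    }

    # -- generic wording, >= 3 nutrients added ----------------------------
    for (r in seq_len(config$counts["generic_fortified"])) {
      g <- pick_group()
      chosen <- sample(all_nut, 3)
      vals <- list()
      for (nut in chosen) {
        sp <- spec_of(nut)
        vals[[nut]] <- round(.applicable_threshold(sp, is_bev(g)) *
                               runif(1, 1.0, 2.0), 4)
      }
      parts <- c(base_list(), sample(tpl$generic_fragments, 1))
      truth <- base_labels("non_fortified"); truth[chosen] <- "fortified"
      expected <- truth
      emit("generic_fortified", g$group, g$subgroup, food_name(),
           paste(parts, collapse = ", "), values = vals,
           truth = truth, expected = expected, compliant = TRUE)
    }

    # -- additive-context decoys ------------------------------------------
    for (r in seq_len(config$counts["additive_decoy"])) {
      nut <- sample(c("calcium", "zinc"), 1)
      g <- pick_group()
      sp <- spec_of(nut)
      thr <- .applicable_threshold(sp, is_bev(g))
      significant <- runif(1) < 0.5
      vals <- list()
      if (significant) {
        vals[[nut]] <- round(thr * runif(1, 1.0, 1.8), 4)
      } else if (runif(1) < 0.5) {
        vals[[nut]] <- round(thr * runif(1, 0.2, 0.8), 4)
      }
      frag <- sprintf(sample(tpl$additive_context_templates, 1),
                      sample(tpl$additive_compound_forms[[nut]], 1))
      parts <- c(base_list(), frag)
      truth <- base_labels("non_fortified")
      expected <- base_labels("non_fortified")
      emit("additive_decoy", g$group, g$subgroup, food_name(),
           paste(parts, collapse = ", "), values = vals,
           truth = truth, expected = expected, compliant = TRUE)
    }

    # -- natural-content remark decoys ------------------------------------
    for (r in seq_len(config$counts["natural_decoy"])) {
      nut <- sample(c("calcium", "zinc", "vitamin_b12"), 1)
      g <- pick_group()
      sp <- spec_of(nut)
      vals <- list()
      vals[[nut]] <- round(.applicable_threshold(sp, is_bev(g)) *
                             runif(1, 1.0, 1.8), 4)
      frag <- sprintf(sample(tpl$natural_remark_templates, 1),
                      tpl$plain_names[[nut]])
      parts <- c(base_list(), frag)
      truth <- base_labels("non_fortified")
      expected <- base_labels("non_fortified")
      emit("natural_decoy", g$group, g$subgroup, food_name(),
           paste(parts, collapse = ", "), values = vals,
           truth = truth, expected = expected, compliant = TRUE)
    }

    # -- mineral-water calcium bait (documented false positive) -----------
    for (r in seq_len(config$counts["mineral_water"])) {
      conc <- sample(60:90, 1)
      frag <- sprintf(tpl$mineral_water_fragment, conc)
      truth <- base_labels("non_fortified")
      expected <- base_labels("non_fortified"); expected["calcium"] <- "fortified"
      emit("mineral_water", "Drinks", NA_character_, "mineraalwater naturel",
           frag, values = list(calcium = conc),
           truth = truth, expected = expected, compliant = FALSE)
    }

    # -- fortificant declared below significance (false negative) ---------
    for (r in seq_len(config$counts["below_significance"])) {
      nut <- "vitamin_b12"
      g <- list(group = "Meat replacers", subgroup = NA_character_)
      sp <- spec_of(nut)
      value <- round(sp$solid_threshold * runif(1, 0.3, 0.9), 4)
      parts <- append(base_list(), sample(tpl$fortificant_forms[[nut]], 1),
                      after = 2)
      truth <- base_labels("non_fortified"); truth[nut] <- "fortified"
      expected <- base_labels("non_fortified")
      emit("below_significance", g$group, g$subgroup,
           "vleesvervanger naturel", paste(parts, collapse = ", "),
           values = setNames(list(value), nut),
           truth = truth, expected = expected, compliant = FALSE)
    }

    # -- fortification wording in legal name / particulars, value missing --
    for (r in seq_len(config$counts["label_fortified"])) {
      nut <- next_nut()
      g <- pick_group()
      name <- food_name()
      plain <- tpl$plain_names[[nut]]
      in_legal <- runif(1) < 0.6
      legal <- if (in_legal) {
        sprintf(sample(tpl$legal_name_fortified_templates, 1), name, plain)
      } else NA_character_
      part <- if (!in_legal) {
        sprintf(sample(tpl$particulars_fortified_templates, 1), plain)
      } else NA_character_
      truth <- base_labels("non_fortified"); truth[nut] <- "fortified"
      expected <- truth
      emit("label_fortified", g$group, g$subgroup, name,
           paste(base_list(), collapse = ", "),
           legal_name = legal, particulars = part,
           truth = truth, expected = expected, compliant = TRUE)
    }

    # -- correctly filed ineligible foods ---------------------------------
    for (r in seq_len(config$counts["ineligible"])) {
      nut <- next_nut()
      sp <- spec_of(nut)
      vals <- list()
      vals[[nut]] <- round(sp$solid_threshold * runif(1, 1.0, 2.5), 4)
      parts <- append(base_list(), sample(tpl$fortificant_forms[[nut]], 1),
                      after = 1)
      emit("ineligible", sample(ineligible_groups_, 1), NA_character_,
           sample(tpl$ineligible_food_names, 1),
           paste(parts, collapse = ", "), values = vals,
           truth = base_labels("ineligible"),
           expected = base_labels("ineligible"), compliant = TRUE)
    }

    # -- ineligible foods mis-filed into an eligible group ----------------
    for (r in seq_len(config$counts["misfiled_ineligible"])) {
      nuts <- sample(all_nut, 2)
      vals <- list()
      parts <- base_list()
      for (nut in nuts) {
        sp <- spec_of(nut)
        vals[[nut]] <- round(sp$solid_threshold * runif(1, 1.0, 2.0), 4)
        parts <- c(parts, sample(tpl$fortificant_forms[[nut]], 1))
      }
      expected <- base_labels("non_fortified"); expected[nuts] <- "fortified"
      emit("misfiled_ineligible", "Milk, milk products, and milk replacers",
           NA_character_, sample(tpl$ineligible_food_names, 1),
           paste(parts, collapse = ", "), values = vals,
           truth = base_labels("ineligible"), expected = expected,
           compliant = FALSE)
    }

    # -- missing food-group classification --------------------------------
    for (r in seq_len(config$counts["missing_group"])) {
      emit("missing_group", NA_character_, NA_character_, food_name(),
           paste(base_list(), collapse = ", "),
           truth = base_labels("non_fortified"),
           expected = base_labels("ineligible"), compliant = FALSE)
    }

    # -- truncated ingredient list ----------------------------------------
    for (r in seq_len(config$counts["truncated"])) {
      nut <- next_nut()
      g <- pick_group()
      sp <- spec_of(nut)
      value <- round(.applicable_threshold(sp, is_bev(g)) *
                       runif(1, 1.0, 2.0), 4)
      form <- sample(setdiff(tpl$fortificant_forms[[nut]],
                             c("b12", "b9", "b11")), 1)
      # three characters never reach the shortest matchable term
      stub <- substr(form, 1, 3)
      parts <- c(base_list(), stub)
      truth <- base_labels("non_fortified"); truth[nut] <- "fortified"
      expected <- base_labels("non_fortified")
      emit("truncated", g$group, g$subgroup, food_name(),
           paste(parts, collapse = ", "),
           values = setNames(list(value), nut),
           truth = truth, expected = expected, compliant = FALSE)
    }

    # -- 1000x value error -------------------------------------------------
    for (r in seq_len(config$counts["value_error"])) {
      nut <- next_nut()
      g <- pick_group()
      sp <- spec_of(nut)
      value <- round(.applicable_threshold(sp, is_bev(g)) *
                       runif(1, 0.2, 0.8) * 1000, 4)
      emit("value_error", g$group, g$subgroup, food_name(),
           paste(base_list(), collapse = ", "),
           values = setNames(list(value), nut),
           truth = base_labels("non_fortified"),
           expected = base_labels("non_fortified"), compliant = FALSE)
    }

    # -- plain fillers -----------------------------------------------------
    for (r in seq_len(config$counts["filler"])) {
      g <- pick_group()
      vals <- list()
      if (runif(1) < 0.4) {
        nut <- next_nut()
        sp <- spec_of(nut)
        vals[[nut]] <- round(.applicable_threshold(sp, is_bev(g)) *
                               runif(1, 0.1, 0.9), 4)
      }
      emit("filler", g$group, g$subgroup, food_name(),
           paste(base_list(), collapse = ", "), values = vals,
           truth = base_labels("non_fortified"),
           expected = base_labels("non_fortified"), compliant = TRUE)
    }

    col <- function(lst, f, what) vapply(lst, `[[`, what, f)
    records <- tibble(
      food_id = col(recs, "food_id", ""),
      food_group = col(recs, "food_group", ""),
      food_subgroup = col(recs, "food_subgroup", ""),
      food_name = col(recs, "food_name", ""),
      ingredient_list = col(recs, "ingredient_list", ""),
      legal_name = col(recs, "legal_name", ""),
      mandatory_particulars = col(recs, "mandatory_particulars", ""),
      calcium = col(recs, "calcium", 0),
      folic_acid = col(recs, "folic_acid", 0),
      dfe = col(recs, "dfe", 0),
      vitamin_b12 = col(recs, "vitamin_b12", 0),
      zinc = col(recs, "zinc", 0),
      single_portion = col(recs, "single_portion", TRUE)
    )
    k <- length(all_nut)
    ground_truth <- tibble(
      food_id = rep(col(gts, "food_id", ""), each = k),
      nutrient = rep(all_nut, times = length(gts)),
      truth = as.vector(vapply(gts, `[[`, character(k), "truth")),
      expected = as.vector(vapply(gts, `[[`, character(k), "expected")),
      scenario = rep(col(gts, "scenario", ""), each = k),
      compliant = rep(col(gts, "compliant", TRUE), each = k)
    )
    perm <- sample(nrow(records))
    records <- records[perm, ]
    ground_truth <- ground_truth[ground_truth$food_id %in% records$food_id, ]
    ground_truth <- ground_truth[order(match(ground_truth$food_id,
                                             records$food_id)), ]
    structure(list(records = records, ground_truth = ground_truth,
                   config = config),
              class = "synth_corpus")
  })
}

#' Expected confusion tables from generator bookkeeping
#'
#' Derives, from the ground-truth ledger alone (never by running the
#' classifier), the per-nutrient 3x3 confusion table the classifier must
#' produce on the generated corpus: rows are the reader's labels (`truth`),
#' columns the labels the decision tree is designed to assign (`expected`).
#'
#' @param corpus A `synth_corpus` from [generate_corpus()].
#' @return Named list (per nutrient) of `contingency_table` matrices.
#' @export
expected_confusion <- function(corpus) {
  stopifnot(inherits(corpus, "synth_corpus"))
  gt <- corpus$ground_truth
  out <- lapply(unique(gt$nutrient), function(nu) {
    d <- gt[gt$nutrient == nu, ]
    build_contingency(d$truth, d$expected)
  })
  names(out) <- unique(gt$nutrient)
  out
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("Synthetic branded-food corpus:", nrow(x$records), "records,",
      length(unique(x$ground_truth$nutrient)), "nutrients\n")
  print(count(x$ground_truth[!duplicated(x$ground_truth$food_id), ],
              .data$scenario))
  invisible(x)
}
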