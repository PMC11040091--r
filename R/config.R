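# Built-in nutrient constants, search-term lexicon, and rule sets.
#
# Everything here is plain data: DRIs and the derived significance cutoffs,
# the Dutch search terms per nutrient, the generic vitamin/mineral wordings,
# the EU functional ingredient class names used to recognise food additives,
# and the food-group lists driving eligibility and beverage determination.
# All of it can be overridden from a YAML file (see
# [read_fortification_config()]), so adding a nutrient is a config change,
# not a code change.

# Daily reference intakes for adults (EU labeling legislation), in the unit
# of the nutrient column.
.default_dri <- c(
  calcium     = 800,   # mg
  folic_acid  = 200,   # ug
  vitamin_b12 = 2.5,   # ug
  zinc        = 10     # mg
)

.default_units <- c(
  calcium = "mg", folic_acid = "ug", vitamin_b12 = "ug", zinc = "mg"
)

# Dutch fortificant search terms per nutrient. Multi-word entries are matched
# as consecutive tokens; single-word entries also match as the leading
# component of longer Dutch compounds ("zink" matches "zinklactaat").
.default_terms <- list(
  calcium = c(
    "calcium", "calciumcarbonaat", "calciumfosfaat", "dicalciumfosfaat",
    "calciumlactaat", "tricalciumcitraat", "calciumcitraat",
    "calciumzouten van orthofosforzuur", "dicalciumdicitraat",
    "calciumhydroxide"
  ),
  folic_acid = c(
    "foliumzuur", "b9", "b11", "folaat", "tetrahydrofolaat", "polyglytamaat",
    "pfteroylmonoglutaminezuur", "folic acid", "folinezuur", "foliumzout"
  ),
  vitamin_b12 = c("b12", "cobalamine", "cyanocobalamine"),
  zinc = c(
    "zink", "zinklactaat", "zink lactaat", "zinksulfaat", "zink sulfaat",
    "zinkoxide", "zink oxide", "zinkgluconaat", "zink gluconaat",
    "zinkcitraat", "zink citraat"
  )
)

# Matches inside these strings are cancelled: calcium-D-pantothenate is a
# chemical form of pantothenic acid, not a calcium fortificant.
.default_exclusions <- list(
  calcium = c("calcium-d-pantothena"),
  folic_acid = character(),
  vitamin_b12 = character(),
  zinc = character()
)

#' Nutrient specifications
#'
#' Builds the per-nutrient constant table used throughout the package: unit,
#' adult daily reference intake (DRI), the two significance cutoffs derived
#' from it (7.5% of DRI per 100 mL for beverages, 15% per 100 g otherwise),
#' and the Dutch search-term lexicon with exclusion patterns.
#'
#' @param nutrients Character vector of nutrient identifiers to include.
#'   The built-ins are `"calcium"`, `"folic_acid"`, `"vitamin_b12"`, `"zinc"`.
#' @param dri Optional named numeric vector overriding the built-in DRIs
#'   (in the nutrient's declared unit). Thresholds are always recomputed as
#'   exact fractions of the DRI.
#' @param terms,exclusions Optional named lists overriding the built-in
#'   search terms / exclusion patterns per nutrient.
#' @param units Optional named character vector of units.
#' @return A tibble with one row per nutrient and columns `nutrient_id`,
#'   `unit`, `dri`, `beverage_threshold`, `solid_threshold`,
#'   `specific_terms` (list), `exclusion_patterns` (list).
#' @examples
#' nutrient_specs()
#' nutrient_specs("zinc")$solid_threshold  # 1.5 mg per 100 g
#' @export
nutrient_specs <- function(nutrients = names(.default_dri),
                           dri = NULL, terms = NULL, exclusions = NULL,
                           units = NULL) {
  dri_all <- .default_dri
  if (!is.null(dri)) dri_all[names(dri)] <- dri
  units_all <- .default_units
  if (!is.null(units)) units_all[names(units)] <- units
  terms_all <- .default_terms
  if (!is.null(terms)) terms_all[names(terms)] <- terms
  excl_all <- .default_exclusions
  if (!is.null(exclusions)) excl_all[names(exclusions)] <- exclusions

  missing_dri <- setdiff(nutrients, names(dri_all))
  if (length(missing_dri) > 0) {
    abort(paste0("No DRI known for nutrient(s): ",
                 paste(missing_dri, collapse = ", "),
                 ". Supply `dri` (and `terms`) for custom nutrients."))
  }
  spec_terms <- lapply(nutrients, function(n) {
    tt <- normalize_label_text(terms_all[[n]] %||% character())
    if (length(tt) == 0) abort(paste0("Empty search-term list for ", n))
    tt
  })
  tibble(
    nutrient_id = nutrients,
    unit = unname(units_all[nutrients]),
    dri = unname(dri_all[nutrients]),
    beverage_threshold = 0.075 * unname(dri_all[nutrients]),
    solid_threshold = 0.15 * unname(dri_all[nutrients]),
    specific_terms = spec_terms,
    exclusion_patterns = lapply(nutrients, function(n)
      normalize_label_text(excl_all[[n]] %||% character()))
  )
}

# The 24 functional ingredient classes of EU 1169/2011 Annex VII Part C:
# Dutch names (matched against ingredient lists) with English equivalents.
.additive_classes <- tibble::tibble(
  dutch = c(
    "zuur", "zuurteregelaar", "antiklontermiddel", "antischuimmiddel",
    "antioxidant", "vulstof", "kleurstof", "emulgator", "smeltzouten",
    "verstevigingsmiddel", "smaakversterker", "meelverbeteraar",
    "schuimmiddel", "geleermiddel", "glansmiddel", "bevochtigingsmiddel",
    "gemodificeerd zetmeel", "conserveermiddel", "drijfgas", "rijsmiddel",
    "complexvormer", "stabilisator", "zoetstof", "verdikkingsmiddel"
  ),
  english = c(
    "acid", "acidity regulator", "anti-caking agent", "anti-foaming agent",
    "antioxidant", "bulking agent", "color", "emulsifier",
    "emulsifying salts", "firming agent", "flavor enhancer",
    "flour treatment agent", "foaming agent", "gelling agent",
    "glazing agent", "humectant", "modified starch", "preservative",
    "propellent gas", "raising agent", "sequestrant", "stabilizer",
    "sweetener", "thickener"
  )
)

# Common spelling/plural variants seen on Dutch labels; matched like the
# canonical class names but kept apart so the canonical set stays exactly
# the 24 legal classes.
.additive_class_variants <- c(
  "stabilisatoren", "emulgatoren", "kleurstoffen", "conserveermiddelen",
  "conserveringsmiddel", "conserveringsmiddelen", "verdikkingsmiddelen",
  "zuurteregelaars", "antioxidanten", "rijsmiddelen", "geleermiddelen",
  "zoetstoffen", "smaakversterkers", "voedingszuur"
)

# Names that disqualify a generic "vitamine(n)/mineralen" match when they
# immediately follow it ("vitamine C" is a specific vitamin, not generic
# wording). The specific terms of all configured nutrients are always added
# to this list at match time.
.qualifier_terms <- c(
  "a", "b", "c", "d", "e", "k",
  "b1", "b2", "b3", "b5", "b6", "b7", "b8", "b12", "d2", "d3", "k1", "k2",
  "ijzer", "jodium", "selenium", "koper", "magnesium", "kalium", "fosfor",
  "mangaan", "chroom", "molybdeen", "fluoride", "chloride", "natrium",
  "biotine", "niacine", "thiamine", "riboflavine", "pantotheenzuur",
  "ascorbinezuur", "retinol", "cholecalciferol", "tocoferol"
)

#' Text-matching lexicon
#'
#' The language resources behind all label-text matching: generic
#' vitamin/mineral wordings, the 24 EU functional ingredient class names
#' (Dutch, with English equivalents), phrases expressing natural content
#' ("bron van", "rijk aan") and fortification ("verrijkt met",
#' "toegevoegd"), the qualifier names that cancel a generic match, and the
#' chemical multiplier prefixes recognised in compound terms.
#'
#' @param generic_terms,additive_classes,additive_class_variants,
#'   natural_content_phrases,fortification_phrases,qualifier_terms,prefixes
#'   Optional overrides for the corresponding built-in sets.
#' @param additive_window,remark_window Token windows used by context
#'   detection: an additive class name governs a nutrient match when it is
#'   one of the `additive_window` tokens immediately before it (with no
#'   ingredient separator in between), and a remark phrase flags a match
#'   when it ends within `remark_window` tokens before it.
#' @return A list of class `fortification_lexicon`.
#' @examples
#' lex <- default_lexicon()
#' nrow(lex$additive_classes)  # 24
#' @export
default_lexicon <- function(generic_terms = NULL,
                            additive_classes = NULL,
                            additive_class_variants = NULL,
                            natural_content_phrases = NULL,
                            fortification_phrases = NULL,
                            qualifier_terms = NULL,
                            prefixes = NULL,
                            additive_window = 3L,
                            remark_window = 3L) {
  lex <- list(
    generic_terms = generic_terms %||% c(
      "vitamine", "vitaminen", "vitamines", "mineralen", "mineraal",
      "vitamines en mineralen", "vitaminen en mineralen",
      "vitamine en mineralen"
    ),
    additive_classes = additive_classes %||% .additive_classes,
    additive_class_variants = additive_class_variants %||%
      .additive_class_variants,
    natural_content_phrases = natural_content_phrases %||% c(
      "bron van", "rijk aan", "natuurlijke bron van", "van nature rijk aan"
    ),
    fortification_phrases = fortification_phrases %||% c(
      "verrijkt met", "verrijkt", "toegevoegd", "toegevoegde",
      "met toegevoegd", "met toegevoegde", "toevoeging van"
    ),
    qualifier_terms = qualifier_terms %||% .qualifier_terms,
    prefixes = prefixes %||% c("mono", "di", "tri", "tetra"),
    additive_window = additive_window,
    remark_window = remark_window
  )
  lex$generic_terms <- normalize_label_text(lex$generic_terms)
  lex$additive_classes$dutch <- normalize_label_text(lex$additive_classes$dutch)
  lex$additive_class_variants <- normalize_label_text(lex$additive_class_variants)
  lex$natural_content_phrases <- normalize_label_text(lex$natural_content_phrases)
  lex$fortification_phrases <- normalize_label_text(lex$fortification_phrases)
  lex$qualifier_terms <- normalize_label_text(lex$qualifier_terms)
  if (nrow(lex$additive_classes) != 24) {
    warn("additive_classes does not contain the 24 EU functional ingredient classes")
  }
  structure(lex, class = "fortification_lexicon")
}

#' Beverage determination rule
#'
#' Beverages take the 7.5%-of-DRI significance cutoff per 100 mL instead of
#' the 15% cutoff per 100 g. Membership is purely categorical: a food is a
#' beverage when its food group is in `beverage_food_groups` or its subgroup
#' is in `beverage_subgroups` (case-insensitive). No inference from names.
#'
#' @param beverage_food_groups,beverage_subgroups Character vectors of group
#'   and subgroup labels.
#' @return A list of class `beverage_rule`.
#' @export
beverage_rule <- function(beverage_food_groups = "Drinks",
                          beverage_subgroups = c(
                            "milk", "chocolate milk", "condensed milk",
                            "coffee milk/cream", "buttermilk", "dairy drinks",
                            "liquid breakfast"
                          )) {
  structure(
    list(
      beverage_food_groups = normalize_label_text(beverage_food_groups),
      beverage_subgroups = normalize_label_text(beverage_subgroups)
    ),
    class = "beverage_rule"
  )
}

#' Eligibility rule
#'
#' Foods governed by legislation other than the general EU labeling rules
#' cannot be assessed by them and are ineligible: foods and formulae for
#' infants and young children, foods for specific medical purposes, total
#' diet replacement for weight control, and food supplements. Foods without
#' a food-group classification are ineligible by default.
#'
#' @param ineligible_groups Character vector of ineligible group labels.
#' @param treat_unclassified_as_ineligible Should a missing food group make
#'   the food ineligible? Default `TRUE`.
#' @return A list of class `eligibility_rule`.
#' @export
eligibility_rule <- function(ineligible_groups = c(
                               "Foods and formulae for infants and young children",
                               "Foods for specific medical purposes",
                               "Total diet replacement for weight control",
                               "Food supplements"
                             ),
                             treat_unclassified_as_ineligible = TRUE) {
  structure(
    list(
      ineligible_groups = normalize_label_text(ineligible_groups),
      treat_unclassified_as_ineligible = isTRUE(treat_unclassified_as_ineligible)
    ),
    class = "eligibility_rule"
  )
}

#' The 21 food groups of the branded-food classification
#'
#' @return Character vector of eligible food-group labels.
#' @export
food_groups <- function() {
  c(
    "Bread", "Bread filling", "Cereals and cereal products",
    "Cheese and cheese substitutes", "Composite meals", "Drinks", "Eggs",
    "Fish, shellfish, crustacean", "Fruit", "Meat replacers",
    "Meat, cold cuts, and poultry", "Milk, milk products, and milk replacers",
    "Miscellaneous", "Nuts and seeds", "Oils and fats",
    "Potatoes and other tubers", "Pulses", "Sauces",
    "Snacks (sweet and savory)", "Soup", "Vegetables"
  )
}

#' Bundle all classification configuration
#'
#' @param specs Nutrient specification tibble, see [nutrient_specs()].
#' @param lexicon Text lexicon, see [default_lexicon()].
#' @param beverage Beverage rule, see [beverage_rule()].
#' @param eligibility Eligibility rule, see [eligibility_rule()].
#' @param search_food_name Should the label-text step (step 7) also search
#'   the food name? Off by default: the legislation's label fields are the
#'   legal name and the mandatory particulars.
#' @return A list of class `fortification_config`.
#' @examples
#' cfg <- fortification_config()
#' cfg$specs$nutrient_id
#' @export
fortification_config <- function(specs = nutrient_specs(),
                                 lexicon = default_lexicon(),
                                 beverage = beverage_rule(),
                                 eligibility = eligibility_rule(),
                                 search_food_name = FALSE) {
  structure(
    list(
      specs = specs, lexicon = lexicon, beverage = beverage,
      eligibility = eligibility, search_food_name = isTRUE(search_food_name)
    ),
    class = "fortification_config"
  )
}

#' Read / write classification configuration as YAML
#'
#' The YAML layout mirrors the configuration objects: a `nutrients` section
#' (one block per nutrient with `unit`, `dri`, `terms`, `exclusions`), a
#' `lexicon` section, `beverage` and `eligibility` sections, and an
#' `options` section. Absent keys fall back to the built-in defaults, so a
#' file may override just one nutrient's terms.
#'
#' @param path Path to a YAML file.
#' @return [read_fortification_config()] returns a `fortification_config`;
#'   [write_fortification_config()] returns `path` invisibly.
#' @export
read_fortification_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  y <- yaml::read_yaml(path)
  nutrients <- names(y$nutrients) %||% names(.default_dri)
  dri <- terms <- excl <- units <- NULL
  if (!is.null(y$nutrients)) {
    dri <- vapply(y$nutrients, function(b) as.numeric(b$dri %||% NA_real_), 0)
    if (anyNA(dri)) {
      abort(paste0("Config nutrient block without a `dri`: ",
                   paste(names(dri)[is.na(dri)], collapse = ", ")))
    }
    units <- vapply(y$nutrients, function(b) b$unit %||% NA_character_, "")
    units <- units[!is.na(units)]
    terms <- lapply(y$nutrients, function(b) as.character(b$terms %||% character()))
    terms <- terms[vapply(terms, length, 0L) > 0]
    excl <- lapply(y$nutrients, function(b) as.character(b$exclusions %||% character()))
  }
  lx <- y$lexicon %||% list()
  lex <- default_lexicon(
    generic_terms = lx$generic_terms,
    additive_classes = if (!is.null(lx$additive_classes))
      tibble(dutch = as.character(lx$additive_classes),
             english = as.character(lx$additive_classes_english %||%
                                      lx$additive_classes)),
    additive_class_variants = lx$additive_class_variants,
    natural_content_phrases = lx$natural_content_phrases,
    fortification_phrases = lx$fortification_phrases,
    qualifier_terms = lx$qualifier_terms,
    additive_window = as.integer(lx$additive_window %||% 3L),
    remark_window = as.integer(lx$remark_window %||% 3L)
  )
  bev <- y$beverage %||% list()
  elig <- y$eligibility %||% list()
  fortification_config(
    specs = nutrient_specs(
      nutrients = nutrients,
      dri = if (length(dri)) dri,
      terms = if (length(terms)) terms,
      exclusions = if (length(excl)) excl,
      units = if (length(units)) units
    ),
    lexicon = lex,
    beverage = beverage_rule(
      beverage_food_groups = bev$food_groups %||% "Drinks",
      beverage_subgroups = bev$subgroups %||% formals(beverage_rule)$beverage_subgroups
    ),
    eligibility = eligibility_rule(
      ineligible_groups = elig$ineligible_groups %||%
        eval(formals(eligibility_rule)$ineligible_groups),
      treat_unclassified_as_ineligible =
        elig$treat_unclassified_as_ineligible %||% TRUE
    ),
    search_food_name = isTRUE((y$options %||% list())$search_food_name)
  )
}

#' @rdname read_fortification_config
#' @param config A `fortification_config` object.
#' @export
write_fortification_config <- function(config, path) {
  stopifnot(inherits(config, "fortification_config"))
  sp <- config$specs
  nutrients <- setNames(lapply(seq_len(nrow(sp)), function(i) {
    list(unit = sp$unit[i], dri = sp$dri[i],
         terms = sp$specific_terms[[i]],
         exclusions = sp$exclusion_patterns[[i]])
  }), sp$nutrient_id)
  lex <- config$lexicon
  yaml::write_yaml(list(
    nutrients = nutrients,
    lexicon = list(
      generic_terms = lex$generic_terms,
      additive_classes = lex$additive_classes$dutch,
      additive_classes_english = lex$additive_classes$english,
      additive_class_variants = lex$additive_class_variants,
      natural_content_phrases = lex$natural_content_phrases,
      fortification_phrases = lex$fortification_phrases,
      qualifier_terms = lex$qualifier_terms,
      additive_window = lex$additive_window,
      remark_window = lex$remark_window
    ),
    beverage = list(
      food_groups = config$beverage$beverage_food_groups,
      subgroups = config$beverage$beverage_subgroups
    ),
    eligibility = list(
      ineligible_groups = config$eligibility$ineligible_groups,
      treat_unclassified_as_ineligible =
        config$eligibility$treat_unclassified_as_ineligible
    ),
    options = list(search_food_name = config$search_food_name)
  ), path)
  invisible(path)
}

.nutrient_value_cols <- c("calcium", "folic_acid", "dfe", "vitamin_b12", "zinc")

#' Check branded-food records for data issues
#'
#' Informational only: classification proceeds regardless, because degraded
#' data (missing groups, missing ingredient lists) is a modeled condition of
#' the decision tree, not an error.
#'
#' @param records A data frame of branded-food records (see
#'   [classify_foods()] for the column contract).
#' @return A tibble with columns `food_id` and `issue`; zero rows when all
#'   records are well formed. Issue codes: `negative_value`,
#'   `non_finite_value`, `unknown_food_group`, `missing_ingredient_list`,
#'   `duplicate_food_id`.
#' @examples
#' validate_records(tibble::tibble(
#'   food_id = "f1", food_group = NA, ingredient_list = "water",
#'   calcium = -5
#' ))
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  out <- list()
  id <- as.character(records$food_id)
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    out <- c(out, list(tibble(food_id = unique(dup), issue = "duplicate_food_id")))
  }
  for (col in intersect(.nutrient_value_cols, names(records))) {
    v <- records[[col]]
    bad_neg <- !is.na(v) & v < 0
    bad_inf <- !is.na(v) & !is.finite(v)
    if (any(bad_neg)) out <- c(out, list(tibble(food_id = id[bad_neg], issue = "negative_value")))
    if (any(bad_inf)) out <- c(out, list(tibble(food_id = id[bad_inf], issue = "non_finite_value")))
  }
  if ("food_group" %in% names(records)) {
    miss <- is.na(records$food_group) | !nzchar(trimws(as.character(records$food_group)))
    if (any(miss)) out <- c(out, list(tibble(food_id = id[miss], issue = "unknown_food_group")))
  }
  if ("ingredient_list" %in% names(records)) {
    miss <- is.na(records$ingredient_list) |
      !nzchar(trimws(as.character(records$ingredient_list)))
    if (any(miss)) out <- c(out, list(tibble(food_id = id[miss], issue = "missing_ingredient_list")))
  }
  if (length(out) == 0) {
    return(tibble(food_id = character(), issue = character()))
  }
  distinct(bind_rows(out))
}
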