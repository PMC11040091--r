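# Nutrient-value significance under EU 1169/2011.
#
# A declared amount is "significant" when it reaches 7.5% of the adult DRI
# per 100 mL for beverages, or 15% per 100 g for everything else. Equality
# counts: the legislation does not require exceeding the percentage. Values
# are taken at face value per 100 g/mL as sold; the script does not
# distinguish single-portion packs (they share the 15% cutoff).

#' Is a food a beverage?
#'
#' Categorical determination only: a food is a beverage when its food group
#' is one of the beverage groups or its subgroup is one of the beverage
#' subgroups (milk drinks, dairy drinks, liquid breakfast, ...). No
#' inference from food names.
#'
#' @param records A data frame with (optionally) `food_group` and
#'   `food_subgroup` columns.
#' @param rule A [beverage_rule()].
#' @return Logical vector, one element per record.
#' @examples
#' is_beverage(tibble::tibble(food_group = c("Drinks", "Bread")))
#' @export
is_beverage <- function(records, rule = beverage_rule()) {
  records <- as_tibble(records)
  grp <- if ("food_group" %in% names(records)) {
    normalize_label_text(as.character(records$food_group))
  } else {
    rep(NA_character_, nrow(records))
  }
  sub <- if ("food_subgroup" %in% names(records)) {
    normalize_label_text(as.character(records$food_subgroup))
  } else {
    rep(NA_character_, nrow(records))
  }
  (!is.na(grp) & grp %in% rule$beverage_food_groups) |
    (!is.na(sub) & sub %in% rule$beverage_subgroups)
}

#' Significance threshold for a nutrient
#'
#' 7.5% of the DRI (per 100 mL) for beverages, 15% of the DRI (per 100 g)
#' otherwise, in the nutrient's declared unit.
#'
#' @param spec One nutrient's specification (single row of
#'   [nutrient_specs()]).
#' @param beverage Logical (vectorised): is the food a beverage?
#' @return Numeric vector of thresholds, one per element of `beverage`.
#' @examples
#' b12 <- dplyr::filter(nutrient_specs(), nutrient_id == "vitamin_b12")
#' significance_threshold(b12, beverage = TRUE)   # 0.1875 ug
#' significance_threshold(b12, beverage = FALSE)  # 0.375 ug
#' @export
significance_threshold <- function(spec, beverage) {
  spec <- as_nutrient_spec(spec)
  stopifnot(spec$dri > 0)
  ifelse(beverage, spec$beverage_threshold, spec$solid_threshold)
}

#' Is a declared nutrient value significant?
#'
#' Inclusive comparison: a value equal to the cutoff is significant.
#'
#' @param value Numeric vector of declared amounts per 100 g/mL.
#' @param spec One nutrient's specification.
#' @param beverage Logical (vectorised, recycled against `value`).
#' @return Logical vector; `NA` where `value` is `NA`.
#' @examples
#' ca <- dplyr::filter(nutrient_specs(), nutrient_id == "calcium")
#' is_significant(c(120, 119.9), ca, beverage = FALSE)
#' @export
is_significant <- function(value, spec, beverage) {
  value >= significance_threshold(spec, beverage)
}

#' All significance thresholds as a table
#'
#' @param specs A [nutrient_specs()] tibble.
#' @return A tibble with columns `nutrient_id`, `unit`, `dri`,
#'   `beverage_threshold`, `solid_threshold`.
#' @export
significance_thresholds <- function(specs = nutrient_specs()) {
  select(specs, all_of(c("nutrient_id", "unit", "dri",
                         "beverage_threshold", "solid_threshold")))
}
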