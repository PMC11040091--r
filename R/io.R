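# CSV readers/writers for branded-food label extracts.
#
# The column layout of real branded-food extracts varies by host
# organisation, so reading goes through a dialect: a column-name map plus a
# decimal-mark flag. Empty cells become absent fields (NA), never zero --
# the decision tree treats "not declared" and "declared 0" differently.

#' CSV dialect for branded-food extracts
#'
#' @param col_map Named character vector mapping canonical column names
#'   (`food_id`, `food_group`, `food_subgroup`, `food_name`,
#'   `ingredient_list`, `legal_name`, `mandatory_particulars`, `calcium`,
#'   `folic_acid`, `dfe`, `vitamin_b12`, `zinc`, `single_portion`) to the
#'   file's header names. Defaults to the identity map.
#' @param decimal_mark `"."` or `","` for numeric cells.
#' @return A list of class `csv_dialect`.
#' @export
csv_dialect <- function(col_map = NULL, decimal_mark = ".") {
  canonical <- c("food_id", "food_group", "food_subgroup", "food_name",
                 "ingredient_list", "legal_name", "mandatory_particulars",
                 .nutrient_value_cols, "single_portion")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  if (!decimal_mark %in% c(".", ",")) abort('`decimal_mark` must be "." or ","')
  structure(list(col_map = map, decimal_mark = decimal_mark),
            class = "csv_dialect")
}

#' Read branded-food records from CSV
#'
#' @param path UTF-8 CSV file.
#' @param dialect A [csv_dialect()].
#' @return A tibble in the [classify_foods()] column contract; empty cells
#'   are `NA` (absent), numeric cells honour the dialect's decimal mark,
#'   and the row count equals the file's data rows.
#' @export
read_food_records <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         locale = readr::locale(encoding = "UTF-8"),
                         progress = FALSE, na = c("", "NA"))
  map <- dialect$col_map
  if (!map[["food_id"]] %in% names(raw)) {
    abort(paste0("Mandatory id column `", map[["food_id"]], "` missing in ", path))
  }
  out <- tibble(.rows = nrow(raw))
  for (canon in names(map)) {
    src <- map[[canon]]
    if (!src %in% names(raw)) next
    v <- raw[[src]]
    if (canon %in% .nutrient_value_cols) {
      if (dialect$decimal_mark == ",") v <- gsub(",", ".", v, fixed = TRUE)
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("Unparseable number in column `", src, "`, row ",
                     bad[1], ": '", v[bad[1]], "'"))
      }
      out[[canon]] <- num
    } else if (canon == "single_portion") {
      out[[canon]] <- tolower(v) %in% c("true", "1", "yes", "ja")
    } else {
      out[[canon]] <- v
    }
  }
  out
}

#' Write branded-food records to CSV
#'
#' Inverse of [read_food_records()]: absent fields become empty cells and
#' numeric precision is preserved, so read -> write -> read round-trips.
#'
#' @param records A records tibble.
#' @param path Output path.
#' @param dialect A [csv_dialect()].
#' @return `path`, invisibly.
#' @export
write_food_records <- function(records, path, dialect = csv_dialect()) {
  records <- as_tibble(records)
  out <- records
  map <- dialect$col_map
  if (dialect$decimal_mark == ",") {
    for (col in intersect(.nutrient_value_cols, names(out))) {
      out[[col]] <- gsub(".", ",", format(out[[col]], digits = 15, trim = TRUE,
                                          scientific = FALSE), fixed = TRUE)
      out[[col]][out[[col]] %in% c("NA", "nan")] <- NA_character_
    }
  }
  present <- intersect(names(map), names(out))
  out <- out[, present]
  names(out) <- unname(map[present])
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write classification results to CSV
#'
#' One row per (food, nutrient) with the label, the terminal step and rule,
#' the per-step outcomes, and (optionally) the compact trace.
#'
#' @param results A `fortification_results` tibble.
#' @param path Output path.
#' @param trace Include a `trace` column (`"1:eligible>2:value_declared>..."`)?
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, trace = FALSE) {
  out <- as_tibble(results)
  if (trace && "trace" %in% names(out)) {
    out$trace <- vapply(out$trace, function(tr) {
      paste(sprintf("%d:%s", tr$step, tr$outcome), collapse = ">")
    }, "")
  } else {
    out$trace <- NULL
  }
  out$label <- as.character(out$label)
  for (st in paste0("step", 1:7)) out[[st]][is.na(out[[st]])] <- "-"
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Coverage and fortification summary of a classified dataset
#'
#' Mirrors how a database-wide run is reported: coverage (fraction of
#' non-missing values) per variable, fortified counts and percentages per
#' nutrient plus the "one or more nutrients" headline (all percentages use
#' the full dataset size as denominator), and fortified counts per food
#' group with groups holding fewer than `merge_below` fortified foods merged
#' into "Miscellaneous".
#'
#' @param results A `fortification_results` tibble covering `records`.
#' @param records The records that were classified.
#' @param merge_below Merge threshold for the per-group table (default 5).
#' @return A list of class `dataset_summary` with tibbles `coverage`,
#'   `per_nutrient`, `per_group`, and scalars `n_foods`,
#'   `n_fortified_any`, `pct_fortified_any`.
#' @export
summarize_fortification <- function(results, records, merge_below = 5) {
  results <- as_tibble(results)
  records <- as_tibble(records)
  n_total <- nrow(records)
  if (!all(as.character(records$food_id) %in% results$food_id) && n_total > 0) {
    abort("`results` must cover every record")
  }

  cov_cols <- intersect(
    c("food_group", "ingredient_list", "legal_name", "mandatory_particulars",
      .nutrient_value_cols),
    names(records)
  )
  coverage <- tibble(
    variable = cov_cols,
    n = vapply(cov_cols, function(cl) {
      v <- records[[cl]]
      sum(!is.na(v) & (!is.character(v) | nzchar(trimws(as.character(v)))))
    }, 0L),
  ) %>% mutate(coverage_pct = pct_of_total(.data$n, n_total))

  fortified <- results %>% filter(.data$label == "fortified")
  per_nutrient <- fortified %>%
    count(nutrient = .data$nutrient, name = "n_fortified") %>%
    tidyr::complete(nutrient = unique(results$nutrient),
                    fill = list(n_fortified = 0L)) %>%
    mutate(pct_of_foods = pct_of_total(.data$n_fortified, n_total))

  n_any <- length(unique(fortified$food_id))

  grp <- records %>%
    mutate(food_id = as.character(.data$food_id)) %>%
    select(all_of(c("food_id",
                    if ("food_group" %in% names(records)) "food_group")))
  if (!"food_group" %in% names(grp)) grp$food_group <- NA_character_
  per_group <- fortified %>%
    distinct(.data$food_id) %>%
    left_join(grp, by = "food_id") %>%
    mutate(food_group = if_else(is.na(.data$food_group), "Unclassified",
                                .data$food_group)) %>%
    count(food_group = .data$food_group, name = "n_fortified") %>%
    mutate(food_group = if_else(.data$n_fortified < merge_below,
                                "Miscellaneous", .data$food_group)) %>%
    group_by(.data$food_group) %>%
    summarise(n_fortified = sum(.data$n_fortified), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_fortified))

  structure(
    list(coverage = coverage, per_nutrient = per_nutrient,
         per_group = per_group, n_foods = n_total, n_fortified_any = n_any,
         pct_fortified_any = pct_of_total(n_any, n_total)),
    class = "dataset_summary"
  )
}

#' Percentage of the full dataset, reporting style
#'
#' `100 * n / total`, rounded half away from zero to `digits` decimals --
#' the arithmetic behind every headline percentage in the summary tables.
#'
#' @param n Count(s).
#' @param total Denominator (the full dataset size).
#' @param digits Decimal places (default 2).
#' @return Numeric vector.
#' @examples
#' pct_of_total(1817, 193742)  # 0.94
#' @export
pct_of_total <- function(n, total, digits = 2) {
  if (total <= 0) return(rep(0, length(n)))
  round_half_up(100 * n / total, digits)
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("Foods: %d; fortified with >= 1 selected nutrient: %d (%.2f%%)\n",
              x$n_foods, x$n_fortified_any, x$pct_fortified_any))
  cat("\nPer nutrient:\n")
  print(x$per_nutrient, n = Inf)
  cat("\nPer food group (groups with < 5 fortified foods merged):\n")
  print(x$per_group, n = Inf)
  cat("\nCoverage:\n")
  print(x$coverage, n = Inf)
  invisible(x)
}
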