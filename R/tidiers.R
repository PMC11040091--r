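# broom-style tidiers for the package's result objects.

#' Tidy a Sison-Glaz interval set
#'
#' @param x A `sison_glaz` object.
#' @param ... Unused.
#' @return A tibble with `category`, `count`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.sison_glaz <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a contingency table
#'
#' @param x A `contingency_table`.
#' @param ... Unused.
#' @return A tibble with `expert_class`, `procedure_class`, `n`.
#' @export
tidy.contingency_table <- function(x, ...) {
  m <- unclass(x)
  tidyr::expand_grid(expert_class = rownames(m),
                     procedure_class = colnames(m)) %>%
    mutate(n = as.integer(t(m))[row_number()])
}

#' Tidy a validation report
#'
#' One row per (nutrient, expert class, procedure class) with the count,
#' the row proportion, and its simultaneous confidence bounds.
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.validation_report <- function(x, ...) {
  bind_rows(lapply(names(x), function(nu) {
    mutate(x[[nu]]$proportions, nutrient = nu, .before = 1)
  }))
}

#' One-line-per-nutrient summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A tibble with `nutrient`, `n`, `agreement` (proportion of foods
#'   on the table diagonal), `sensitivity`, `specificity`, `conf.level`.
#' @export
glance.validation_report <- function(x, ...) {
  bind_rows(lapply(names(x), function(nu) {
    m <- unclass(x[[nu]]$table)
    tibble(
      nutrient = nu,
      n = sum(m),
      agreement = sum(diag(m)) / sum(m),
      sensitivity = x[[nu]]$sensitivity,
      specificity = x[[nu]]$specificity,
      conf.level = attr(x, "conf.level")
    )
  }))
}
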