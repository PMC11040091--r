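# ggplot2 displays for the result objects.

#' Plot a fortification summary
#'
#' Bar chart of fortified foods per food group (the per-group table with
#' small groups already merged into Miscellaneous).
#'
#' @param object A `dataset_summary` from [summarize_fortification()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dataset_summary <- function(object, ...) {
  d <- object$per_group
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$food_group, .data$n_fortified),
    y = .data$n_fortified
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Fortified foods",
      title = sprintf("%d of %d foods fortified (%.2f%%)",
                      object$n_fortified_any, object$n_foods,
                      object$pct_fortified_any)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Row proportions of each expert class with their simultaneous confidence
#' intervals, faceted by nutrient.
#'
#' @param object A `validation_report` from [validate_classification()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$procedure_class, y = .data$estimate,
    colour = .data$expert_class
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~nutrient) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "Procedure label", y = "Row proportion",
      colour = "Expert label",
      title = sprintf("Expert vs procedure (%.0f%% simultaneous CIs)",
                      100 * attr(object, "conf.level"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-step tally
#'
#' How many foods answered "yes" at each decision-tree step, per nutrient.
#'
#' @param tally A tibble from [step_tally()].
#' @return A ggplot object.
#' @export
plot_step_tally <- function(tally) {
  d <- tally %>%
    select(all_of(c("nutrient", paste0("yes", 1:7)))) %>%
    tidyr::pivot_longer(-"nutrient", names_to = "step", values_to = "yes",
                        names_prefix = "yes") %>%
    mutate(step = as.integer(.data$step))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$step), y = .data$yes,
                                  fill = .data$nutrient)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Decision-tree step", y = 'Foods answering "yes"',
                  fill = NULL) +
    ggplot2::theme_minimal()
}
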