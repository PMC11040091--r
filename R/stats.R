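# Validation mathematics: expert-vs-procedure contingency tables,
# sensitivity/specificity, and Sison-Glaz simultaneous confidence intervals
# for multinomial proportions.
#
# The Sison-Glaz (1995) procedure finds the smallest integer half-width c
# such that the probability that every multinomial count lies within c of
# its observed value reaches 1 - alpha, approximating that probability by a
# product of doubly-truncated Poisson terms with an Edgeworth-corrected
# density for their sum. The intervals are
#   [p_i - c/n, p_i + c/n + 2*gamma/n], truncated to [0, 1],
# with gamma interpolating between nu(c) and nu(c + 1).

#' Round half away from zero
#'
#' Report-style rounding (95.25 -> 95.3), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# central moments (and normalising mass) of a Poisson(lambda) truncated to
# [lambda - c, lambda + c]; the window has at most 2c + 1 support points so
# the moments are computed directly from the probabilities
.truncpois_moments <- function(cc, lambda) {
  supp <- max(0, lambda - cc):(lambda + cc)
  w <- dpois(supp, lambda)
  den <- sum(w)
  if (den <= 0) return(c(0, 0, 0, 0, den = 0))
  p <- w / den
  m1 <- sum(supp * p)
  d <- supp - m1
  c(m1, sum(d^2 * p), sum(d^3 * p), sum(d^4 * p), den = den)
}

# nu(c): Sison-Glaz approximation to P(all |N_i - n_i| <= c) for a
# multinomial with cell probabilities n_i / n. Can exceed 1 slightly and is
# NaN when every truncated cell is degenerate (c = 0 on extreme tables).
.sg_nu <- function(cc, counts) {
  n <- sum(counts)
  s1 <- s2 <- s3 <- s4 <- 0
  dens <- 1
  for (l in counts) {
    m <- .truncpois_moments(cc, l)
    s1 <- s1 + m[1]
    s2 <- s2 + m[2]
    s3 <- s3 + m[3]
    s4 <- s4 + (m[4] - 3 * m[2]^2)  # fourth cumulant adds over cells
    dens <- dens * m["den"]
  }
  if (s2 <= 0) return(NaN)
  z <- (n - s1) / sqrt(s2)
  g1 <- s3 / s2^1.5
  g2 <- s4 / s2^2
  poly <- 1 + g1 * (z^3 - 3 * z) / 6 + g2 * (z^4 - 6 * z^2 + 3) / 24 +
    g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72
  edgeworth <- poly * exp(-z^2 / 2) / sqrt(2 * pi)
  unname(dens * edgeworth / sqrt(s2) / dpois(n, n))
}

#' Sison-Glaz simultaneous confidence intervals
#'
#' Simultaneous (1 - alpha) confidence intervals for all categories of a
#' multinomial proportion vector. The half-width search skips degenerate
#' non-finite values of the coverage approximation (which occur at c = 0 for
#' one-cell tables), treating them as zero coverage; this reproduces the
#' conventional behaviour on rows like (91, 0, 0).
#'
#' @param counts Non-negative integer vector of category counts; must sum to
#'   at least 1.
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @return An object of class `sison_glaz`: a tibble with columns
#'   `category`, `count`, `estimate`, `conf.low`, `conf.high`, carrying
#'   attributes `c`, `gamma`, and `conf.level`. Intervals always contain
#'   their point estimates and are truncated to [0, 1].
#' @examples
#' sison_glaz(c(101, 4, 1))
#' @references Sison, C.P. and Glaz, J. (1995). Simultaneous confidence
#'   intervals and sample size determination for multinomial proportions.
#'   JASA 90(429), 366-369.
#' @export
sison_glaz <- function(counts, alpha = 0.05) {
  cat_names <- names(counts) %||% as.character(seq_along(counts))
  counts <- as.numeric(counts)
  if (any(is.na(counts) | counts < 0 | counts != floor(counts))) {
    abort("`counts` must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("`counts` must sum to at least 1")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  target <- 1 - alpha
  nu_prev <- 0
  cc <- NA_integer_
  gamma <- NA_real_
  for (ci in 0:n) {
    nu <- .sg_nu(ci, counts)
    if (!is.finite(nu)) next
    if (nu >= target) {
      cc <- ci - 1L
      gamma <- (target - nu_prev) / (nu - nu_prev)
      break
    }
    nu_prev <- nu
  }
  if (is.na(cc)) {
    # coverage target never reached within the support: widest interval
    cc <- as.integer(n)
    gamma <- 0
  }
  p <- counts / n
  out <- tibble(
    category = cat_names,
    count = counts,
    estimate = p,
    conf.low = pmax(p - cc / n, 0),
    conf.high = pmin(p + cc / n + 2 * gamma / n, 1)
  )
  structure(out, c = cc, gamma = gamma, conf.level = 1 - alpha,
            class = c("sison_glaz", class(out)))
}

#' Row proportions with simultaneous confidence intervals
#'
#' Convenience wrapper around [sison_glaz()] mirroring how a contingency-
#' table row is reported: point estimate and simultaneous CI per category.
#'
#' @param row_counts Non-negative integer vector (one contingency row).
#' @param alpha Significance level.
#' @return The [sison_glaz()] tibble.
#' @export
row_proportions_with_ci <- function(row_counts, alpha = 0.05) {
  sison_glaz(row_counts, alpha = alpha)
}

#' Build an expert-vs-procedure contingency table
#'
#' @param expert,procedure Vectors (character or factor) of labels over
#'   `fortified`, `non_fortified`, `ineligible`, paired element-wise (same
#'   foods in the same order, e.g. after joining on `food_id`).
#' @return A 3x3 integer matrix of class `contingency_table`; rows are
#'   expert classes, columns procedure classes, in the fixed order
#'   (fortified, non_fortified, ineligible).
#' @examples
#' build_contingency(c("fortified", "fortified", "ineligible"),
#'                   c("fortified", "non_fortified", "ineligible"))
#' @export
build_contingency <- function(expert, procedure) {
  if (length(expert) != length(procedure)) {
    abort("`expert` and `procedure` must pair the same foods (equal length)")
  }
  expert <- as.character(expert)
  procedure <- as.character(procedure)
  bad <- unique(c(setdiff(expert, .labels), setdiff(procedure, .labels)))
  if (length(bad) > 0) {
    abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  tab <- table(factor(expert, levels = .labels),
               factor(procedure, levels = .labels))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(expert = .labels, procedure = .labels))
  structure(m, class = c("contingency_table", "matrix", "array"))
}

.as_contingency <- function(table) {
  if (inherits(table, "contingency_table")) return(unclass(table))
  m <- as.matrix(table)
  if (!all(dim(m) == c(3, 3))) abort("expected a 3x3 contingency table")
  m
}

#' Sensitivity of the automated procedure
#'
#' True-positive rate: of the foods the experts call fortified, the fraction
#' the procedure also calls fortified. By the reporting convention used
#' here, foods the procedure ruled ineligible are excluded from the
#' denominator (set `exclude_ineligible = FALSE` to include them).
#'
#' @param table A `contingency_table` (expert rows, procedure columns).
#' @param exclude_ineligible Drop procedure-ineligible foods from the
#'   denominator? Default `TRUE`.
#' @return Proportion in [0, 1].
#' @examples
#' tab <- matrix(c(242, 10, 1, 0, 220, 12, 0, 0, 0), 3, byrow = TRUE)
#' sensitivity(tab)  # 242 / 252
#' @export
sensitivity <- function(table, exclude_ineligible = TRUE) {
  m <- .as_contingency(table)
  denom <- m[1, 1] + m[1, 2] + if (exclude_ineligible) 0 else m[1, 3]
  if (denom == 0) abort("no expert-fortified foods in the denominator")
  m[1, 1] / denom
}

#' Specificity of the automated procedure
#'
#' True-negative rate: of the foods the experts call non-fortified, the
#' fraction the procedure also calls non-fortified. By the reporting
#' convention used here, procedure-ineligible foods stay in the denominator
#' (set `include_ineligible = FALSE` to drop them).
#'
#' @inheritParams sensitivity
#' @param include_ineligible Keep procedure-ineligible foods in the
#'   denominator? Default `TRUE`.
#' @return Proportion in [0, 1].
#' @examples
#' tab <- matrix(c(101, 4, 1, 10, 357, 12, 12, 0, 3), 3, byrow = TRUE)
#' specificity(tab)  # 357 / 379
#' @export
specificity <- function(table, include_ineligible = TRUE) {
  m <- .as_contingency(table)
  denom <- m[2, 1] + m[2, 2] + if (include_ineligible) m[2, 3] else 0
  if (denom == 0) abort("no expert-non-fortified foods in the denominator")
  m[2, 2] / denom
}

#' Validate procedure labels against expert labels
#'
#' Joins predictions and reference labels on (`food_id`, `nutrient`), builds
#' the per-nutrient 3x3 contingency table, row proportions with Sison-Glaz
#' simultaneous confidence intervals, and sensitivity/specificity.
#'
#' @param predictions A data frame with `food_id`, `nutrient`, and a label
#'   column (`label`, as produced by [classify_foods()]).
#' @param truth A data frame with `food_id`, `nutrient`, and the reference
#'   label in a column named `truth` or `label`.
#' @param alpha Significance level for the simultaneous intervals.
#' @return An object of class `validation_report`: a named list (one entry
#'   per nutrient) with elements `table` (contingency), `proportions`
#'   (tidy per-row CIs), `sensitivity`, `specificity`; plus attribute
#'   `conf.level`. Use [tidy()], [glance()], [autoplot()] on it.
#' @export
validate_classification <- function(predictions, truth, alpha = 0.05) {
  predictions <- as_tibble(predictions)
  truth <- as_tibble(truth)
  truth_col <- if ("truth" %in% names(truth)) "truth" else "label"
  tr <- truth %>%
    select(food_id = all_of("food_id"), nutrient = all_of("nutrient"),
           truth = all_of(truth_col)) %>%
    mutate(food_id = as.character(.data$food_id))
  pr <- predictions %>%
    select(food_id = all_of("food_id"), nutrient = all_of("nutrient"),
           label = all_of("label")) %>%
    mutate(food_id = as.character(.data$food_id))
  joined <- dplyr::inner_join(tr, pr, by = c("food_id", "nutrient"))
  if (nrow(joined) < nrow(tr) || nrow(joined) < nrow(pr)) {
    abort("unpaired records: predictions and truth must cover the same (food_id, nutrient) pairs")
  }
  nutrients <- unique(joined$nutrient)
  rep <- lapply(nutrients, function(nu) {
    d <- joined[joined$nutrient == nu, ]
    tab <- build_contingency(d$truth, d$label)
    props <- bind_rows(lapply(.labels, function(cl) {
      row <- unclass(tab)[cl, ]
      if (sum(row) == 0) return(NULL)
      ci <- sison_glaz(row, alpha = alpha)
      mutate(as_tibble(ci), expert_class = cl, .before = 1)
    }))
    list(
      table = tab,
      proportions = rename(props, procedure_class = "category"),
      sensitivity = tryCatch(sensitivity(tab), error = function(e) NA_real_),
      specificity = tryCatch(specificity(tab), error = function(e) NA_real_)
    )
  })
  names(rep) <- nutrients
  structure(rep, conf.level = 1 - alpha, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Expert vs procedure validation (",
      format(100 * attr(x, "conf.level")), "% simultaneous CIs)\n", sep = "")
  for (nu in names(x)) {
    cat("\n== ", nu, " ==\n", sep = "")
    print(unclass(x[[nu]]$table))
    cat(sprintf("sensitivity %.3f, specificity %.3f\n",
                x[[nu]]$sensitivity, x[[nu]]$specificity))
  }
  invisible(x)
}

#' Write a validation report as a table-shaped CSV
#'
#' One row per (nutrient, expert class), one column block per procedure
#' class formatted as `n (pct%) CI: lo-hi%`, percentages rounded half away
#' from zero to one decimal.
#'
#' @param report A `validation_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  fmt_cell <- function(count, est, lo, hi) {
    sprintf("%d (%.1f%%) CI: %.1f-%.1f%%", as.integer(count),
            round_half_up(100 * est, 1), round_half_up(100 * lo, 1),
            round_half_up(100 * hi, 1))
  }
  rows <- list()
  for (nu in names(report)) {
    pr <- report[[nu]]$proportions
    for (cl in unique(pr$expert_class)) {
      d <- pr[pr$expert_class == cl, ]
      cells <- setNames(
        vapply(.labels, function(pc) {
          r <- d[d$procedure_class == pc, ]
          if (nrow(r) == 0) return("")
          fmt_cell(r$count, r$estimate, r$conf.low, r$conf.high)
        }, ""),
        paste0("procedure_", .labels)
      )
      rows <- c(rows, list(c(
        nutrient = nu, expert_class = cl, total = sum(d$count), cells
      )))
    }
  }
  out <- as_tibble(do.call(rbind, rows))
  readr::write_csv(out, path)
  invisible(path)
}
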