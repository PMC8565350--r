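#' Trend test via the 95% confidence interval of a regression slope
#'
#' Ordinary least-squares regression of a per-image metric on an
#' experimental variable, with the trend decision read off the t-based 95%
#' confidence interval of the gradient: `increasing` when the lower bound
#' is above 0, `decreasing` when the upper bound is below 0, otherwise
#' `no_trend`. This is the criterion used to call, e.g., decreasing
#' colocalization with increasing salt.
#'
#' @param x Numeric experimental variable (>= 3 distinct values).
#' @param y Numeric metric values, same length as `x`.
#' @param variable Name of the variable (for reporting).
#' @return Object of class `trend_result` (one-row tibble): `variable`,
#'   `slope`, `ci_low`, `ci_high`, `n`, `decision`. A [tidy()] method
#'   returns it as a plain tibble.
#' @export
#' @examples
#' trend_test(1:6, 2 * (1:6))$decision  # "increasing", CI width 0
trend_test <- function(x, y, variable = "x") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(unique(x)) < 3) {
    abort("need >= 3 distinct values of the experimental variable.")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)["x"])
  s <- suppressWarnings(summary(fit)$sigma)
  if (s <= 1e-10 * (max(abs(y)) + 1)) {
    ci <- c(slope, slope) # numerically perfect fit: degenerate CI
  } else {
    ci <- as.numeric(confint(fit, "x", level = 0.95))
  }
  decision <- if (ci[1] > 0) {
    "increasing"
  } else if (ci[2] < 0) {
    "decreasing"
  } else {
    "no_trend"
  }
  out <- tibble(
    variable = variable, slope = slope,
    ci_low = ci[1], ci_high = ci[2],
    n = length(x), decision = decision
  )
  class(out) <- c("trend_result", class(out))
  out
}

#' @rdname trend_test
#' @param x For `tidy.trend_result`, a `trend_result`.
#' @param ... Unused.
#' @export
tidy.trend_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test as used for pairwise condition
#' comparisons: exact enumeration when both groups have <= 20 observations
#' and the data contain no ties, otherwise the tie-corrected normal
#' approximation (with continuity correction). The reported statistic is
#' the Mann-Whitney U of the first group; the two-sided p-value is
#' symmetric under swapping the groups.
#'
#' @param a,b Numeric vectors (each >= 3 values).
#' @param group_a,group_b Group labels for reporting.
#' @return One-row tibble: `group_a`, `group_b`, `statistic`, `p_value`,
#'   `mean_difference` (`mean(a) - mean(b)`), `method`.
#' @export
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(10, 11, 12))$p_value  # exact 0.1
rank_sum_compare <- function(a, b, group_a = "a", group_b = "b") {
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs >= 3 values.")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && length(a) <= 20 && length(b) <= 20
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)
  )
  tibble(
    group_a = group_a, group_b = group_b,
    statistic = unname(ht$statistic),
    p_value = min(ht$p.value, 1),
    mean_difference = mean(a) - mean(b),
    method = if (use_exact) "exact" else "normal_approx"
  )
}

#' Pool per-image colocalization ratios across conditions
#'
#' Mean and SD of the per-image `C_R` values over every condition in scope,
#' with an optional exclusion (e.g. dropping an extreme-pH condition from
#' the pooled estimate). Pooling is over images, not over condition means.
#'
#' @param results Per-image tibble with `condition_id` and `C_R` columns.
#' @param exclude Either `NULL`, a character vector of condition ids to
#'   drop, or a predicate function on `condition_id` returning `TRUE` for
#'   conditions to drop.
#' @return One-row tibble: `mean`, `sd` (0 when a single value remains),
#'   `n`, `n_conditions`.
#' @export
pooled_summary <- function(results, exclude = NULL) {
  if (!all(c("condition_id", "C_R") %in% names(results))) {
    abort("`results` needs columns `condition_id` and `C_R`.")
  }
  keep <- rep(TRUE, nrow(results))
  if (is.character(exclude)) {
    keep <- !(results$condition_id %in% exclude)
  } else if (is.function(exclude)) {
    keep <- !vapply(results$condition_id, exclude, TRUE)
  } else if (!is.null(exclude)) {
    abort("`exclude` must be NULL, condition ids, or a predicate function.")
  }
  vals <- results$C_R[keep]
  if (length(vals) == 0) abort("no values remain after exclusion.")
  tibble(
    mean = mean(vals),
    sd = if (length(vals) > 1) sd(vals) else 0,
    n = length(vals),
    n_conditions = length(unique(results$condition_id[keep]))
  )
}

#' Holm-adjusted pairwise rank-sum comparisons
#'
#' Convenience wrapper running [rank_sum_compare()] for every pair of
#' groups in a long table. Unadjusted p-values are primary (matching how
#' pairwise condition tests are usually reported); Holm-adjusted values
#' are added when `adjust = TRUE`.
#'
#' @param data Data frame with a grouping column and a value column.
#' @param group,value Column names (strings).
#' @param adjust Add a `p_adjusted` (Holm) column.
#' @return Tibble with one row per unordered group pair.
#' @export
pairwise_rank_sum <- function(data, group, value, adjust = FALSE) {
  g <- as.character(data[[group]])
  v <- data[[value]]
  levels <- unique(g)
  if (length(levels) < 2) abort("need at least two groups.")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  out <- purrr::map(pairs, function(p) {
    rank_sum_compare(v[g == p[1]], v[g == p[2]],
                     group_a = p[1], group_b = p[2])
  }) |>
    dplyr::bind_rows()
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}
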