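.stat_result <- function(method, statistic, df = NA_real_, p_value,
                         estimate = NA_real_, n = NA_integer_,
                         context = NA_character_) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = unname(estimate), n = as.integer(n),
                 context = context)
}

#' Kruskal-Wallis test of group location differences
#'
#' Rank-based H statistic with tie correction against a chi-square reference;
#' the workhorse for comparing metric and ordinal sleepiness measures across
#' the four subgroups.
#'
#' @param data data frame.
#' @param value unquoted column of values.
#' @param group unquoted column of group labels (>= 2 non-empty groups).
#' @return one-row tibble (`method`, `statistic`, `df`, `p_value`, `n`).
#' @examples
#' kruskal_wallis(data.frame(y = c(1, 2, 3, 4, 5, 6),
#'                           g = rep(c("a", "b"), each = 3)), y, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("need at least two non-empty groups")
  ht <- kruskal.test(v, g)
  .stat_result("Kruskal-Wallis", ht$statistic, ht$parameter, ht$p.value,
               n = length(v))
}

#' Spearman rank correlation with significance test
#'
#' Rank correlation using average ranks for ties; the p-value uses the exact
#' small-sample null distribution (Edgeworth-corrected) when there are no
#' ties and n < 1290, and the t approximation otherwise.
#'
#' @param data data frame.
#' @param x,y unquoted paired columns (n >= 4 complete pairs).
#' @return one-row tibble with `estimate` (rho), `statistic` (S), `p_value`,
#'   `n`.
#' @export
spearman_with_p <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 4) abort("need at least 4 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation undefined for a constant vector")
  }
  ht <- suppressWarnings(cor.test(xv, yv, method = "spearman"))
  .stat_result("Spearman", ht$statistic, p_value = ht$p.value,
               estimate = ht$estimate, n = length(xv))
}

#' Fisher-z test for the difference of two independent correlations
#'
#' Tests whether a correlation estimated in one subgroup differs from the
#' same correlation estimated in an independent subgroup:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.
#'
#' @param r1,r2 correlations from independent groups, `|r| < 1`.
#' @param n1,n2 group sizes (>= 4).
#' @return one-row tibble with `statistic` (z), `p_value`, `estimate`
#'   (`r1 - r2`).
#' @examples
#' correlation_difference_test(0.5, 50, 0.0, 50)
#' @export
correlation_difference_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("|r| must be < 1")
  if (n1 < 4 || n2 < 4) abort("each group needs n >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  .stat_result("Fisher-z correlation difference", z,
               p_value = 2 * pnorm(-abs(z)), estimate = r1 - r2,
               n = n1 + n2)
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Two-sided rank-sum test with tie correction; the exact null enumeration
#' is used for small tie-free samples (combined n <= 20), the normal
#' approximation otherwise.
#'
#' @param data data frame.
#' @param value unquoted column of values.
#' @param group unquoted column with exactly two non-empty levels.
#' @return one-row tibble (`statistic` = W, `p_value`, `n`).
#' @export
rank_sum_test <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) abort("need exactly two non-empty groups")
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  if (all(v == v[1])) {
    # degenerate: every observation tied -> no evidence of a shift
    return(.stat_result("Wilcoxon rank-sum",
                        c(W = length(x) * length(y) / 2),
                        p_value = 1, n = length(v)))
  }
  exact <- length(v) <= 20 && !any(duplicated(v))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact))
  .stat_result("Wilcoxon rank-sum", ht$statistic, p_value = ht$p.value,
               n = length(v))
}
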