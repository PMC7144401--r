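.kw_p <- function(data, col) {
  kruskal_wallis(data, !!rlang::sym(col), group)$p_value
}

#' Group-wise descriptive tables of the sleepiness battery
#'
#' Four descriptive views of a subject-level cohort table, one row per
#' variable, group-wise summaries in columns, and an uncorrected
#' between-group test p-value (Kruskal-Wallis for metric/ordinal variables,
#' chi-square for categorical ones):
#'
#' * `describe_metric()`: mean and SD of age, VAS pre/post, the three change
#'   scores, SSD, SSQ, ESS;
#' * `describe_categorical()`: counts and percentages of gender and ASLEEP;
#' * `describe_ordinal()`: median and IQR of KSS and SSS pre/post;
#' * `describe_arousal()`: mean and SD of the stage-time proportions, MVV
#'   and ASS.
#'
#' @param cohort subject-level tibble with a `group` column (HC/OB/DEP/OBDEP).
#' @return a tibble in long layout (`variable`, `group`, summaries) joined
#'   with a per-variable `p_value` column.
#' @export
describe_metric <- function(cohort) {
  vars <- c(age = "age", vas_pre = "vas_pre", vas_post = "vas_post",
            d_vas = "d_vas", d_kss = "d_kss", d_sss = "d_sss",
            ssd = "ssd", ssq = "ssq", ess_total = "ess_total")
  vars <- vars[vars %in% names(cohort)]
  purrr::map_dfr(vars, function(v) {
    cohort |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data[[v]], na.rm = TRUE),
                       sd = sd(.data[[v]], na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::mutate(p_value = .kw_p(cohort, v))
  })
}

#' @rdname describe_metric
#' @export
describe_ordinal <- function(cohort) {
  vars <- c("kss_pre", "kss_post", "sss_pre", "sss_post")
  vars <- vars[vars %in% names(cohort)]
  purrr::map_dfr(vars, function(v) {
    cohort |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(median = median(.data[[v]], na.rm = TRUE),
                       q25 = quantile(.data[[v]], 0.25, na.rm = TRUE),
                       q75 = quantile(.data[[v]], 0.75, na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::mutate(p_value = .kw_p(cohort, v))
  })
}

#' @rdname describe_metric
#' @export
describe_categorical <- function(cohort) {
  vars <- c("gender", "asleep")
  vars <- vars[vars %in% names(cohort)]
  purrr::map_dfr(vars, function(v) {
    p <- tryCatch(
      suppressWarnings(chisq.test(table(cohort$group,
                                        cohort[[v]]))$p.value),
      error = function(e) NA_real_)
    cohort |>
      dplyr::count(.data$group, level = as.character(.data[[v]])) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::mutate(p_value = p)
  })
}

#' @rdname describe_metric
#' @export
describe_arousal <- function(cohort) {
  vars <- c("prop_0", "prop_a", "prop_b", "prop_c", "mvv", "ass")
  vars <- vars[vars %in% names(cohort)]
  purrr::map_dfr(vars, function(v) {
    cohort |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data[[v]], na.rm = TRUE),
                       sd = sd(.data[[v]], na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::mutate(p_value = .kw_p(cohort, v))
  })
}

#' Group-wise objective-by-subjective Spearman correlation table
#'
#' Computes, within each subgroup (and optionally overall), the Spearman
#' correlation of every objective arousal measure with every subjective
#' sleepiness measure, with its uncorrected significance test.
#'
#' @param cohort subject-level tibble.
#' @param objective,subjective character vectors of column names (defaults:
#'   the canonical variable sets).
#' @param overall also include an `ALL` pseudo-group (default TRUE).
#' @return tibble with columns `group`, `objective`, `subjective`, `rho`,
#'   `p_value`, `n`.
#' @export
correlation_table <- function(cohort,
                              objective = sleepiness_variable_sets()$objective,
                              subjective = sleepiness_variable_sets()$subjective,
                              overall = TRUE) {
  groups <- split(cohort, cohort$group, drop = TRUE)
  if (overall) groups <- c(list(ALL = cohort), groups)
  purrr::imap_dfr(groups, function(df, gname) {
    purrr::map_dfr(objective, function(o) {
      purrr::map_dfr(subjective, function(s) {
        res <- tryCatch(
          spearman_with_p(df, !!rlang::sym(o), !!rlang::sym(s)),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        tibble::tibble(group = gname, objective = o, subjective = s,
                       rho = res$estimate, p_value = res$p_value,
                       n = res$n)
      })
    })
  })
}

#' Compare one subjective-objective correlation between two subgroups
#'
#' Convenience wrapper: estimates the Spearman correlation of `x` and `y`
#' separately in two subgroups and applies the Fisher-z
#' [correlation_difference_test()].
#'
#' @param cohort subject-level tibble with a `group` column.
#' @param x,y unquoted column names.
#' @param groups character vector of two group labels to compare.
#' @return one-row tibble with the two correlations, their difference, z and
#'   p-value.
#' @export
compare_group_correlation <- function(cohort, x, y, groups) {
  if (length(groups) != 2) abort("`groups` must name exactly two groups")
  sub <- lapply(groups, function(g) cohort[cohort$group == g, , drop = FALSE])
  r <- lapply(sub, function(df) spearman_with_p(df, {{ x }}, {{ y }}))
  res <- correlation_difference_test(r[[1]]$estimate, r[[1]]$n,
                                     r[[2]]$estimate, r[[2]]$n)
  tibble::tibble(group_1 = groups[1], group_2 = groups[2],
                 r_1 = r[[1]]$estimate, r_2 = r[[2]]$estimate,
                 difference = res$estimate, statistic = res$statistic,
                 p_value = res$p_value)
}

#' Boxplots of subjective and objective sleepiness by subgroup
#'
#' @param cohort subject-level tibble.
#' @param vars character vector of columns to display.
#' @return a ggplot object.
#' @export
plot_group_profiles <- function(cohort,
                                vars = c("kss_pre", "sss_pre", "vas_pre",
                                         "ess_total", "mvv", "ass")) {
  vars <- vars[vars %in% names(cohort)]
  long <- tidyr::pivot_longer(cohort[c("group", vars)], -"group",
                              names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
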