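# build the interaction design shared by the Gaussian and the
# proportional-odds models: dv ~ age + gender + ssq +
#   depressed * obese * objective (all two-way terms and the three-way term)
.interaction_terms <- function(objective) {
  c("depressed", "obese", objective,
    paste0("depressed:", "obese"),
    paste0("depressed:", objective),
    paste0("obese:", objective),
    paste0("depressed:obese:", objective))
}

.interaction_frame <- function(data, dv, objective) {
  needed <- c(dv, objective, "age", "gender", "ssq")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("depressed", "obese") %in% names(data))) {
    if (!"group" %in% names(data)) {
      abort("need either `depressed`/`obese` indicators or a `group` column")
    }
    data$depressed <- data$group %in% c("DEP", "OBDEP")
    data$obese <- data$group %in% c("OB", "OBDEP")
  }
  df <- data[c(needed, "depressed", "obese")]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$gender <- factor(df$gender)
  df$depressed <- as.logical(df$depressed)
  df$obese <- as.logical(df$obese)
  df
}

# sequential-drop tests: the three-way term against the full model, then
# each two-way term against the model without the three-way term
.drop_scheme <- function(objective) {
  full <- paste0("depressed * obese * ", objective)
  no3 <- sprintf("(depressed + obese + %s)^2", objective)
  list(
    list(term = paste0("depressed:obese:", objective),
         full = full, reduced = no3),
    list(term = paste0("depressed:", objective), full = no3,
         reduced = sprintf("(depressed + obese + %s)^2 - depressed:%s",
                           objective, objective)),
    list(term = paste0("obese:", objective), full = no3,
         reduced = sprintf("(depressed + obese + %s)^2 - obese:%s",
                           objective, objective)),
    list(term = "depressed:obese", full = no3,
         reduced = sprintf("(depressed + obese + %s)^2 - depressed:obese",
                           objective))
  )
}

.model_formula <- function(dv, rhs) {
  as.formula(paste0(dv, " ~ age + gender + ssq + ", rhs))
}

#' Gaussian interaction regression of a metric sleepiness measure
#'
#' Least-squares regression of a metric subjective measure (VAS, ESS) on
#' age, gender and sleep quality (SSQ) plus main effects, all two-way
#' interactions and the three-way interaction of depression status, obesity
#' status and one objective arousal measure (MVV or ASS).  Moderation —
#' heterogeneity of the subjective-objective association across subgroups —
#' is assessed by F-tests from sequential term drops: the three-way term is
#' tested against the full model, each two-way term against the model
#' without the three-way term.
#'
#' @param data subject-level data frame; needs the dv and objective columns,
#'   `age`, `gender`, `ssq`, and either logical `depressed`/`obese` columns
#'   or a `group` factor (HC/OB/DEP/OBDEP).
#' @param dv name of the metric dependent variable (e.g. `"vas_pre"`,
#'   `"ess_total"`).
#' @param objective name of the objective measure (`"mvv"` or `"ass"`).
#' @return object of class `vigil_lm_interaction`: list with the fitted
#'   `lm` (`fit`), the F-test table (`tests`: term, df, F, p_value) and the
#'   complete-case count; has [tidy()] and [glance()] methods.
#' @export
fit_linear_interaction_model <- function(data, dv, objective = "mvv") {
  df <- .interaction_frame(data, dv, objective)
  fit <- lm(.model_formula(dv, paste0("depressed * obese * ", objective)),
            data = df)
  al <- alias(fit)$Complete
  if (!is.null(al)) {
    abort(paste0("collinear design; aliased terms: ",
                 paste(rownames(al), collapse = ", ")))
  }
  tests <- dplyr::bind_rows(lapply(.drop_scheme(objective), function(sc) {
    f1 <- lm(.model_formula(dv, sc$full), data = df)
    f0 <- lm(.model_formula(dv, sc$reduced), data = df)
    a <- anova(f0, f1)
    tibble::tibble(term = sc$term, df = a$Df[2],
                   statistic = a$F[2], p_value = a$`Pr(>F)`[2])
  }))
  structure(list(fit = fit, tests = tests, dv = dv, objective = objective,
                 n = nrow(df)),
            class = "vigil_lm_interaction")
}

#' @export
print.vigil_lm_interaction <- function(x, ...) {
  cat(sprintf("Gaussian interaction model: %s ~ ... %s (n = %d)\n",
              x$dv, x$objective, x$n))
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_linear_interaction_model
#' @param x,object a `vigil_lm_interaction`.
#' @param ... ignored.
#' @export
tidy.vigil_lm_interaction <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname fit_linear_interaction_model
#' @export
glance.vigil_lm_interaction <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n,
                 df_residual = x$fit$df.residual)
}

#' Proportional-odds interaction regression of an ordinal measure
#'
#' Cumulative-logit model (shared slopes across thresholds) for ordinal
#' subjective measures (KSS, SSS, ASLEEP) with the same predictor set as
#' [fit_linear_interaction_model()].  Interaction effects are assessed by
#' likelihood-ratio chi-square tests from the same sequential-drop scheme.
#'
#' @inheritParams fit_linear_interaction_model
#' @param dv name of the ordinal dependent variable; must show at least 3
#'   distinct levels in the complete cases.
#' @return object of class `vigil_po_interaction`: list with the fitted
#'   `MASS::polr` object (`fit`), the LR test table (`tests`: term, df,
#'   lr_statistic, p_value) and `n`; has [tidy()] and [glance()] methods.
#' @export
fit_proportional_odds <- function(data, dv, objective = "mvv") {
  df <- .interaction_frame(data, dv, objective)
  lev <- sort(unique(df[[dv]]))
  if (length(lev) < 3) {
    abort(sprintf("`%s` has %d observed levels; need at least 3",
                  dv, length(lev)))
  }
  df[[dv]] <- factor(df[[dv]], levels = lev, ordered = TRUE)
  fit_po <- function(rhs) {
    f <- tryCatch(
      suppressWarnings(
        MASS::polr(.model_formula(dv, rhs), data = df, Hess = TRUE)),
      error = function(e) abort(paste0(
        "proportional-odds fit failed (possible separation or ",
        "non-convergence): ", conditionMessage(e)))
    )
    if (f$convergence != 0) {
      abort("proportional-odds fit did not converge")
    }
    f
  }
  fit <- fit_po(paste0("depressed * obese * ", objective))
  tests <- dplyr::bind_rows(lapply(.drop_scheme(objective), function(sc) {
    f1 <- fit_po(sc$full)
    f0 <- fit_po(sc$reduced)
    lr <- 2 * (logLik(f1) - logLik(f0))
    dfree <- attr(logLik(f1), "df") - attr(logLik(f0), "df")
    tibble::tibble(term = sc$term, df = dfree,
                   statistic = as.numeric(lr),
                   p_value = pchisq(as.numeric(lr), dfree,
                                    lower.tail = FALSE))
  }))
  structure(list(fit = fit, tests = tests, dv = dv, objective = objective,
                 n = nrow(df)),
            class = "vigil_po_interaction")
}

#' @export
print.vigil_po_interaction <- function(x, ...) {
  cat(sprintf("Proportional-odds interaction model: %s ~ ... %s (n = %d)\n",
              x$dv, x$objective, x$n))
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_proportional_odds
#' @param x,object a `vigil_po_interaction`.
#' @param ... ignored.
#' @export
tidy.vigil_po_interaction <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  kind <- c(rep("coefficient", length(coef(x$fit))),
            rep("threshold", nrow(s) - length(coef(x$fit))))
  tibble::tibble(term = rownames(s), kind = kind, estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3])
}

#' @rdname fit_proportional_odds
#' @export
glance.vigil_po_interaction <- function(x, ...) {
  tibble::tibble(log_lik = as.numeric(logLik(x$fit)),
                 aic = stats::AIC(x$fit),
                 n = x$n, edf = attr(logLik(x$fit), "df"))
}
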