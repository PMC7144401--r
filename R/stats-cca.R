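#' The canonical subjective and objective variable sets
#'
#' Column names of the two blocks entering the canonical correlation
#' analysis: the ten subjective sleepiness measures (situational scales pre
#' and post EEG, their change scores, and the ordinal ASLEEP self-report)
#' and the six objective arousal parameters (stage-time proportions, mean
#' vigilance value, arousal stability score).
#'
#' @return named list with character vectors `subjective` and `objective`.
#' @export
sleepiness_variable_sets <- function() {
  list(
    subjective = c("sss_pre", "kss_pre", "vas_pre", "sss_post", "kss_post",
                   "vas_post", "d_sss", "d_kss", "d_vas", "asleep"),
    objective = c("prop_0", "prop_a", "prop_b", "prop_c", "mvv", "ass")
  )
}

.block_matrix <- function(data, vars, name) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s block: missing columns %s", name,
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[vars])
  storage.mode(m) <- "double"
  m
}


#' Canonical correlation with a bootstrap Pillai-Bartlett trace test
#'
#' Measures the global association between the subjective and objective
#' sleepiness blocks.  Both blocks are standardized (complete cases only),
#' the canonical correlations are extracted, and the Pillai-Bartlett trace
#' (sum of squared canonical correlations) is tested against a resampled
#' null distribution: each replication permutes the rows of the objective
#' block, which breaks the between-block association while preserving each
#' block's internal correlation structure.  The p-value uses the add-one
#' formula `(1 + #(trace* >= trace)) / (replications + 1)`.
#'
#' The canonical subjective set is exactly collinear by construction (each
#' change score equals post minus pre), so by default each block is reduced
#' to an orthonormal basis of its column space (effective rank) before the
#' decomposition; `on_rank_deficiency = "error"` instead fails, naming the
#' offending block.
#'
#' @param data data frame with one row per subject.
#' @param subjective,objective character vectors of column names; defaults
#'   are the canonical variable sets of [sleepiness_variable_sets()].
#' @param replications number of resampling replications (default 9999).
#' @param seed integer seed for the permutation draw.
#' @param on_rank_deficiency `"project"` (default: analyse the block's
#'   column space) or `"error"`.
#' @return object of class `vigil_cca` with fields
#'   `canonical_correlations`, `pillai`, `p_value`, `null_trace`,
#'   `replications`, `n`; has [tidy()], [glance()] and [autoplot()] methods.
#' @export
cca_pillai_bootstrap <- function(data,
                                 subjective = sleepiness_variable_sets()$subjective,
                                 objective = sleepiness_variable_sets()$objective,
                                 replications = 9999, seed = 1L,
                                 on_rank_deficiency = c("project", "error")) {
  on_rank_deficiency <- match.arg(on_rank_deficiency)
  x <- .block_matrix(data, subjective, "subjective")
  y <- .block_matrix(data, objective, "objective")
  keep <- stats::complete.cases(x, y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep, , drop = FALSE]
  n <- nrow(x)
  if (n <= ncol(x) + ncol(y)) {
    abort("need more subjects than the total number of block variables")
  }
  # orthonormal column-space basis of a standardized block
  basis <- function(m, name) {
    m <- scale(m)
    m[, !is.finite(colSums(m))] <- 0       # constant columns carry no signal
    s <- svd(m)
    r <- sum(s$d > max(s$d) * 1e-8)
    if (r < ncol(m) && on_rank_deficiency == "error") {
      abort(paste0("rank-deficient ", name,
                   " block: drop collinear variables"))
    }
    if (r == 0) abort(paste0(name, " block has no variation"))
    s$u[, seq_len(r), drop = FALSE]
  }
  qx <- basis(x, "subjective")
  qy <- basis(y, "objective")
  cors <- pmin(svd(crossprod(qx, qy))$d, 1)
  pillai <- sum(cors^2)

  # row-permuting Y permutes the rows of its orthonormal basis, so each
  # replication only needs a small cross-product and SVD
  set.seed(seed)
  null_trace <- vapply(seq_len(replications), function(b) {
    sum(pmin(svd(crossprod(qx, qy[sample.int(n), , drop = FALSE]))$d, 1)^2)
  }, 0)
  p <- (1 + sum(null_trace >= pillai)) / (replications + 1)

  structure(
    list(canonical_correlations = cors, pillai = pillai, p_value = p,
         null_trace = null_trace, replications = replications, n = n,
         subjective = subjective, objective = objective),
    class = "vigil_cca"
  )
}

#' @export
print.vigil_cca <- function(x, ...) {
  cat(sprintf(
    "Canonical correlation, bootstrap Pillai-Bartlett trace test\n n = %d, %d x %d variables\n Pillai trace = %.4f, p = %.4g (%d replications)\n",
    x$n, length(x$subjective), length(x$objective), x$pillai, x$p_value,
    x$replications))
  cat(" canonical correlations:",
      paste(sprintf("%.3f", x$canonical_correlations), collapse = " "), "\n")
  invisible(x)
}

#' @rdname cca_pillai_bootstrap
#' @param x a `vigil_cca` object.
#' @param ... ignored.
#' @export
tidy.vigil_cca <- function(x, ...) {
  tibble::tibble(dimension = seq_along(x$canonical_correlations),
                 canonical_correlation = x$canonical_correlations,
                 squared = x$canonical_correlations^2)
}

#' @rdname cca_pillai_bootstrap
#' @export
glance.vigil_cca <- function(x, ...) {
  tibble::tibble(pillai = x$pillai, p_value = x$p_value, n = x$n,
                 replications = x$replications,
                 n_dimensions = length(x$canonical_correlations))
}

#' @rdname cca_pillai_bootstrap
#' @param object a `vigil_cca` object.
#' @export
autoplot.vigil_cca <- function(object, ...) {
  df <- tibble::tibble(trace = object$null_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trace)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$pillai, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "Pillai-Bartlett trace (resampled null)", y = "count",
                  title = sprintf("observed trace %.3f, p = %.4g",
                                  object$pillai, object$p_value)) +
    ggplot2::theme_minimal()
}
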