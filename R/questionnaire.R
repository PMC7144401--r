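#' Score the Epworth Sleepiness Scale (ESS)
#'
#' Eight items, each rated 0 (would never doze) to 3 (high chance of dozing);
#' the total ranges 0-24 and totals above 10 indicate excessive daytime
#' sleepiness (EDS).
#'
#' @param items integer vector of 8 item responses, each in 0-3, or a matrix /
#'   data frame with 8 columns (one row per subject).
#' @return tibble with columns `ess_total` (0-24) and `eds` (logical,
#'   `ess_total > 10`).
#' @examples
#' score_ess(c(3, 3, 3, 2, 0, 0, 0, 0))
#' @export
score_ess <- function(items) {
  m <- .item_matrix(items, n_items = 8L, range = c(0L, 3L), what = "ESS")
  total <- as.integer(rowSums(m))
  tibble::tibble(ess_total = total, eds = total > 10L)
}

#' Subjective sleep quality (SSQ) from SF-A restedness items
#'
#' The restedness subscale has 8 adjectives rated 1 (not at all) to
#' 5 (very much); SSQ is the item mean (sum / 8), range 1-5, higher = more
#' rested after the previous night's sleep.
#'
#' @param items integer vector of 8 item responses in 1-5, or a matrix / data
#'   frame with 8 columns.
#' @return numeric vector of SSQ values.
#' @examples
#' compute_ssq(rep(5, 8))  # 5
#' @export
compute_ssq <- function(items) {
  m <- .item_matrix(items, n_items = 8L, range = c(1L, 5L),
                    what = "restedness")
  unname(rowSums(m) / 8)
}

.item_matrix <- function(items, n_items, range, what) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1L)
  if (ncol(items) != n_items) {
    abort(sprintf("%s requires exactly %d items, got %d",
                  what, n_items, ncol(items)))
  }
  if (anyNA(items)) abort(sprintf("%s items contain missing values", what))
  if (any(items < range[1] | items > range[2]) ||
      any(items != round(items))) {
    abort(sprintf("%s items must be integers in %d-%d",
                  what, range[1], range[2]))
  }
  items
}

.instrument_ranges <- list(
  kss = c(1, 10), sss = c(1, 7), vas = c(0, 100)
)

#' Pre/post change scores for the situational sleepiness scales
#'
#' The KSS (1-10), SSS (1-7) and VAS (0-100) are administered immediately
#' before and after the resting EEG; the change score is `post - pre`
#' (positive = sleepier after the recording).
#'
#' @param pre,post numeric vectors on the same instrument's scale.
#' @param scale one of `"kss"`, `"sss"`, `"vas"`; used for range validation.
#' @return numeric vector `post - pre`.
#' @examples
#' delta_scores(3, 4, "kss")   #  1
#' delta_scores(5, 2, "sss")   # -3
#' @export
delta_scores <- function(pre, post, scale = c("kss", "sss", "vas")) {
  scale <- match.arg(scale)
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have the same length")
  }
  rng <- .instrument_ranges[[scale]]
  ok <- function(x) all(is.na(x) | (x >= rng[1] & x <= rng[2]))
  if (!ok(pre) || !ok(post)) {
    abort(sprintf("%s values must lie in %g-%g", toupper(scale),
                  rng[1], rng[2]))
  }
  post - pre
}

#' Obesity/depression subgroup from BMI and BDI-II
#'
#' Subjects are cross-classified by the WHO obesity cut-off (BMI >= 30
#' kg/m^2) and the BDI-II depression cut-off (score >= 14):
#' `HC` (neither), `OB` (obese only), `DEP` (depressed only), `OBDEP` (both).
#' The boundary values BMI = 30 and BDI-II = 14 fall in the obese and
#' depressed categories respectively.
#'
#' @param bmi numeric body-mass index in kg/m^2 (> 0).
#' @param bdi integer BDI-II total in 0-63.
#' @return factor with levels `HC`, `OB`, `DEP`, `OBDEP`.
#' @examples
#' classify_group(c(24, 45, 24, 45), c(4, 5, 24, 24))
#' @export
classify_group <- function(bmi, bdi) {
  if (length(bmi) != length(bdi)) {
    abort("`bmi` and `bdi` must have the same length")
  }
  if (any(bmi <= 0, na.rm = TRUE)) abort("BMI must be positive")
  if (any(bdi < 0 | bdi > 63, na.rm = TRUE)) {
    abort("BDI-II scores must lie in 0-63")
  }
  obese <- bmi >= 30
  depressed <- bdi >= 14
  out <- dplyr::case_when(
    !obese & !depressed ~ "HC",
    obese & !depressed ~ "OB",
    !obese & depressed ~ "DEP",
    obese & depressed ~ "OBDEP"
  )
  factor(out, levels = c("HC", "OB", "DEP", "OBDEP"))
}

#' Validate and score a raw subject questionnaire table
#'
#' Takes a one-row-per-subject table holding raw questionnaire fields
#' (`ess_1`..`ess_8`, `rest_1`..`rest_8`, `kss_pre`, `kss_post`, `sss_pre`,
#' `sss_post`, `vas_pre`, `vas_post`, `asleep`, `ssd`, `bmi`, `bdi`, `age`,
#' `gender`) and returns the scored table with `ess_total`, `eds`, `ssq`,
#' `d_kss`, `d_sss`, `d_vas` and the `group` label appended.  Validation is
#' strict: any out-of-range or missing item fails with the offending row
#' numbers; rows are never imputed.
#'
#' @param data data frame of raw per-subject fields.
#' @return tibble with derived score columns appended.
#' @export
score_subject_table <- function(data) {
  required <- c(paste0("ess_", 1:8), paste0("rest_", 1:8),
                "kss_pre", "kss_post", "sss_pre", "sss_post",
                "vas_pre", "vas_post", "asleep", "ssd", "bmi", "bdi",
                "age", "gender")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  check_rows <- function(ok, what) {
    if (!all(ok)) {
      abort(sprintf("invalid %s in row(s): %s", what,
                    paste(which(!ok), collapse = ", ")))
    }
  }
  in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  ess_items <- as.matrix(data[paste0("ess_", 1:8)])
  rest_items <- as.matrix(data[paste0("rest_", 1:8)])
  check_rows(rowSums(!in_range(ess_items, 0, 3)) == 0, "ESS items")
  check_rows(rowSums(!in_range(rest_items, 1, 5)) == 0, "restedness items")
  check_rows(in_range(data$kss_pre, 1, 10) & in_range(data$kss_post, 1, 10),
             "KSS")
  check_rows(in_range(data$sss_pre, 1, 7) & in_range(data$sss_post, 1, 7),
             "SSS")
  check_rows(in_range(data$vas_pre, 0, 100) & in_range(data$vas_post, 0, 100),
             "VAS")
  check_rows(in_range(data$asleep, 1, 4), "ASLEEP")
  check_rows(in_range(data$ssd, 0, 24 * 60), "SSD")
  check_rows(in_range(data$bmi, 10, 100), "BMI")
  check_rows(in_range(data$bdi, 0, 63), "BDI-II")

  out <- tibble::as_tibble(data)
  ess <- score_ess(ess_items)
  out$ess_total <- ess$ess_total
  out$eds <- ess$eds
  out$ssq <- compute_ssq(rest_items)
  out$d_kss <- delta_scores(out$kss_pre, out$kss_post, "kss")
  out$d_sss <- delta_scores(out$sss_pre, out$sss_post, "sss")
  out$d_vas <- delta_scores(out$vas_pre, out$vas_post, "vas")
  out$group <- classify_group(out$bmi, out$bdi)
  out
}
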