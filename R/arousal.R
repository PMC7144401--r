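#' Stage-time proportions of a vigilance sequence
#'
#' Fraction of unmasked recording time spent in stage 0, the A stages
#' (A1+A2+A3), the B stages (B1+B2/3), and stage C.  Artifact seconds are
#' excluded from both numerator and denominator, so the four proportions
#' always sum to one.
#'
#' @param sequence a [stage_sequence()] (or anything coercible to one).
#' @return one-row tibble with columns `prop_0`, `prop_a`, `prop_b`, `prop_c`.
#' @examples
#' stage_proportions(stage_sequence(c(rep("0", 3), rep("C", 3))))
#' @export
stage_proportions <- function(sequence) {
  s <- unmasked_stages(sequence)
  if (length(s) == 0L) abort("all seconds are masked as artifacts")
  tibble::tibble(
    prop_0 = mean(s == "0"),
    prop_a = mean(s %in% c("A1", "A2", "A3")),
    prop_b = mean(s %in% c("B1", "B2/3")),
    prop_c = mean(s == "C")
  )
}

#' Mean vigilance value (MVV)
#'
#' Arithmetic mean of the per-second vigilance scores (stage 0 = 7 down to
#' stage C = 1) over all unmasked seconds; range 1 to 7.  Reported unrounded;
#' round only for display.
#'
#' @inheritParams stage_proportions
#' @return numeric scalar in \[1, 7\].
#' @examples
#' mean_vigilance_value(stage_sequence(rep("A2", 1200)))  # 5
#' @export
mean_vigilance_value <- function(sequence) {
  s <- unmasked_stages(sequence)
  if (length(s) == 0L) abort("all seconds are masked as artifacts")
  mean(stage_score(s))
}

#' Arousal stability score (ASS)
#'
#' An 11-point ordinal summary of how quickly and how deeply arousal declines
#' over a resting recording.  The criteria form a precedence cascade from the
#' least to the most stable pattern:
#'
#' * scores 1-3: at least one stage-C second occurred; the score is set by the
#'   minute bin of first C emergence (1-5 / 6-10 / 11-15 -> 1 / 2 / 3);
#' * scores 4-6: no C, but at least one third of unmasked seconds are B2/3;
#'   score by the first-B2/3 minute bin (4 / 5 / 6);
#' * scores 7-9: no C, B2/3 below one third, but at least one third of
#'   unmasked seconds are B stages; score by the first-B minute bin (7/8/9);
#' * score 10-11: rigid arousal regulation; 11 if only stages 0 and A1 occur,
#'   10 otherwise (only 0/A stages, or B present but below the one-third
#'   share).
#'
#' The cascade is checked from C downwards because the criteria are not
#' mutually exclusive (every B2/3 second is also a B second); lower score =
#' less stable.  Minute bins are wall-clock minutes including masked seconds;
#' the one-third shares are computed over unmasked seconds only.  First
#' emergence after the last bin boundary (minutes 16-20 of a 20-minute
#' recording) is mapped to the last bin.
#'
#' @inheritParams stage_proportions
#' @param bin_breaks increasing integer vector of three upper minute-bin
#'   boundaries; the default `c(5, 10, 15)` reproduces the standard bins of a
#'   15-20-minute recording.
#' @param seconds_per_minute seconds per wall-clock minute bin (default 60;
#'   smaller values give scaled "minutes" for short test sequences).
#' @return integer score in 1..11, with attribute `note` flagging the
#'   conventions applied (late emergence mapped to the last bin; sub-third B
#'   share scored 10).
#' @examples
#' # rigid regulation, A stages only
#' arousal_stability_score(stage_sequence(rep(c("0", "A1", "A2"), 400)))
#' @export
arousal_stability_score <- function(sequence, bin_breaks = c(5, 10, 15),
                                    seconds_per_minute = 60) {
  sequence <- as_stage_sequence(sequence)
  if (length(bin_breaks) != 3L || any(diff(bin_breaks) <= 0)) {
    abort("`bin_breaks` must be three increasing minute boundaries")
  }
  keep <- !sequence$artifact
  if (!any(keep)) abort("all seconds are masked as artifacts")
  s <- sequence$stage[keep]
  minute <- ceiling(sequence$second / seconds_per_minute)

  bin_of <- function(m) {
    if (m <= bin_breaks[1]) 1L else if (m <= bin_breaks[2]) 2L else 3L
  }
  first_minute <- function(stages) {
    hit <- keep & sequence$stage %in% stages
    minute[which(hit)[1]]
  }

  note <- character()
  n <- length(s)
  n_b23 <- sum(s == "B2/3")
  n_b <- sum(s %in% c("B1", "B2/3"))

  score <- if (any(s == "C")) {
    m <- first_minute("C")
    if (m > bin_breaks[3]) note <- c(note, "first emergence after last bin")
    bin_of(m)                 # 1 / 2 / 3
  } else if (n_b23 >= n / 3) {
    m <- first_minute("B2/3")
    if (m > bin_breaks[3]) note <- c(note, "first emergence after last bin")
    3L + bin_of(m)            # 4 / 5 / 6
  } else if (n_b >= n / 3) {
    m <- first_minute(c("B1", "B2/3"))
    if (m > bin_breaks[3]) note <- c(note, "first emergence after last bin")
    6L + bin_of(m)            # 7 / 8 / 9
  } else if (all(s %in% c("0", "A1"))) {
    11L
  } else {
    if (n_b > 0) note <- c(note, "B stages present below one-third share")
    10L
  }
  structure(as.integer(score), note = note)
}

#' Summarize a stage sequence into the objective sleepiness parameters
#'
#' Convenience wrapper returning stage proportions, mean vigilance value and
#' arousal stability score as a single one-row tibble (one row per subject
#' when mapped over a cohort).
#'
#' @inheritParams arousal_stability_score
#' @return one-row tibble with columns `prop_0`, `prop_a`, `prop_b`,
#'   `prop_c`, `mvv`, `ass`, `n_artifact`.
#' @export
arousal_summary <- function(sequence, bin_breaks = c(5, 10, 15),
                            seconds_per_minute = 60) {
  sequence <- as_stage_sequence(sequence)
  out <- stage_proportions(sequence)
  out$mvv <- mean_vigilance_value(sequence)
  out$ass <- as.integer(arousal_stability_score(
    sequence, bin_breaks = bin_breaks, seconds_per_minute = seconds_per_minute
  ))
  out$n_artifact <- sum(sequence$artifact)
  out
}
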