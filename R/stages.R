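#' The seven EEG-vigilance stages
#'
#' EEG-vigilance grades tonic brain arousal from high alertness down to sleep
#' onset.  Seven stages are distinguished on a one-second grid:
#'
#' | stage  | score | characteristic                                          |
#' |--------|-------|---------------------------------------------------------|
#' | `0`    | 7     | low-voltage EEG, no alpha, no slow eye movements        |
#' | `A1`   | 6     | predominant occipital alpha activity                    |
#' | `A2`   | 5     | high temporal and parietal alpha activity               |
#' | `A3`   | 4     | predominant frontal alpha activity                      |
#' | `B1`   | 3     | low-voltage EEG with slow horizontal eye movements      |
#' | `B2/3` | 2     | increased delta and theta power                         |
#' | `C`    | 1     | K-complexes and sleep spindles (sleep onset)            |
#'
#' `vigilance_stages()` returns the stage alphabet in descending arousal
#' order; `stage_score()` maps stage labels to their numeric scores (7 =
#' highest arousal, 1 = sleep onset).  Artifact-bearing seconds carry the
#' reserved label `"ARTIFACT"` and have no score.
#'
#' @param stage character vector of stage labels.
#' @return `vigilance_stages()`: character vector of length 7.
#'   `stage_score()`: integer vector, `NA` for `"ARTIFACT"`.
#' @examples
#' vigilance_stages()
#' stage_score(c("0", "A2", "C"))
#' @export
vigilance_stages <- function() {
  c("0", "A1", "A2", "A3", "B1", "B2/3", "C")
}

.stage_scores <- c("0" = 7L, "A1" = 6L, "A2" = 5L, "A3" = 4L,
                   "B1" = 3L, "B2/3" = 2L, "C" = 1L)

#' @rdname vigilance_stages
#' @export
stage_score <- function(stage) {
  bad <- !stage %in% c(names(.stage_scores), "ARTIFACT")
  if (any(bad)) {
    abort(paste0("unknown stage label(s): ",
                 paste(unique(stage[bad]), collapse = ", ")))
  }
  unname(.stage_scores[stage])
}

#' Build a per-second stage sequence
#'
#' A stage sequence is the backbone object connecting the EEG to all
#' objective sleepiness metrics: one vigilance label per second of recording,
#' plus a logical artifact mask.  Masked seconds carry the label
#' `"ARTIFACT"` and are excluded from every downstream summary.
#'
#' @param stage character vector of stage labels (one per second).
#' @param artifact logical vector (recycled) marking artifact seconds.
#' @return a tibble of class `stage_sequence` with columns `second` (1-based),
#'   `stage` and `artifact`.
#' @examples
#' stage_sequence(rep("A1", 5))
#' @export
stage_sequence <- function(stage, artifact = FALSE) {
  stage <- as.character(stage)
  artifact <- rep_len(as.logical(artifact), length(stage))
  artifact <- artifact | stage == "ARTIFACT"
  stage[artifact] <- "ARTIFACT"
  bad <- !stage %in% c(vigilance_stages(), "ARTIFACT")
  if (any(bad)) {
    abort(paste0("unknown stage label(s): ",
                 paste(unique(stage[bad]), collapse = ", ")))
  }
  tibble::new_tibble(
    list(second = seq_along(stage), stage = stage, artifact = artifact),
    class = "stage_sequence"
  )
}

as_stage_sequence <- function(x) {
  if (inherits(x, "stage_sequence")) return(x)
  if (is.data.frame(x) && all(c("stage", "artifact") %in% names(x))) {
    return(stage_sequence(x$stage, x$artifact))
  }
  if (is.character(x)) return(stage_sequence(x))
  abort("cannot interpret input as a stage sequence")
}

unmasked_stages <- function(sequence) {
  sequence <- as_stage_sequence(sequence)
  sequence$stage[!sequence$artifact]
}

#' Read and write stage-sequence tables
#'
#' Sequences are stored as plain tab-separated tables with columns
#' `second`, `stage`, `artifact` so that staging output can be archived and
#' re-analysed without the raw EEG.
#'
#' @param sequence a `stage_sequence`.
#' @param path file path.
#' @return `read_stage_sequence()` returns a `stage_sequence`;
#'   `write_stage_sequence()` returns `path` invisibly.
#' @export
write_stage_sequence <- function(sequence, path) {
  sequence <- as_stage_sequence(sequence)
  utils::write.table(as.data.frame(sequence), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_sequence
#' @export
read_stage_sequence <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "logical"))
  stage_sequence(df$stage, df$artifact)
}

#' Hypnogram-style plot of a stage sequence
#'
#' Plots the vigilance score (7 = high alertness, 1 = sleep onset) against
#' time; artifact seconds are shown as gaps with a rug underneath.
#'
#' @param object a `stage_sequence`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.stage_sequence <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$score <- ifelse(df$artifact, NA_integer_, stage_score(df$stage))
  df$minute <- df$second / 60
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$minute, y = .data$score)) +
    ggplot2::geom_step(na.rm = TRUE, colour = "#2c5f8a") +
    ggplot2::scale_y_continuous(
      breaks = 7:1, labels = vigilance_stages(), limits = c(1, 7),
      name = "EEG-vigilance stage"
    ) +
    ggplot2::labs(x = "time [min]") +
    ggplot2::theme_minimal()
  if (any(df$artifact)) {
    p <- p + ggplot2::geom_rug(
      data = df[df$artifact, ], sides = "b", colour = "firebrick",
      ggplot2::aes(y = NULL)
    )
  }
  p
}
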