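#' Read a recording from EDF or a delimited signal table
#'
#' Dispatches on the file extension (`.edf` vs anything else) unless
#' `format` is given, validates the montage, and optionally decimates to a
#' lower analysis rate with an anti-aliasing filter
#' ([signal::decimate()], 8th-order Chebyshev type-I low-pass applied
#' forward and backward).
#'
#' @param path file path.
#' @param format `"auto"`, `"edf"` or `"table"`.
#' @param region_map optional named character vector `channel -> region`
#'   overriding the name-based inference (EDF only; tables carry their map).
#' @param analysis_rate optional target sampling rate in Hz; must divide the
#'   file's rate.
#' @return an [eeg_recording()] in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "table"),
                           region_map = NULL, analysis_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
      else "table"
  }
  rec <- switch(format,
                edf = read_edf(path, region_map),
                table = read_recording_table(path))
  if (!is.null(analysis_rate) && analysis_rate != rec$sampling_rate) {
    q <- rec$sampling_rate / analysis_rate
    if (abs(q - round(q)) > 1e-9 || q < 1) {
      abort(sprintf("analysis_rate %g must divide the file rate %g",
                    analysis_rate, rec$sampling_rate))
    }
    q <- as.integer(round(q))
    dec <- t(apply(rec$signal, 1, function(x) {
      signal::decimate(x, q, ftype = "iir")
    }))
    rec <- eeg_recording(dec, analysis_rate, rec$montage, rec$start_time)
  }
  rec
}

#' Pipeline configuration
#'
#' @param input_mode `"simulate"` (generate a cohort) or `"files"` (read a
#'   scored subject table and staged sequences from disk).
#' @param sim a [sim_config()] (simulate mode).
#' @param subject_table path to a raw subject questionnaire table
#'   (files mode; CSV, columns as in [score_subject_table()]).
#' @param sequence_dir directory of per-subject stage-sequence tables named
#'   `<id>.tsv` (files mode).
#' @param stage_recordings logical: in simulate mode, synthesize EEG and run
#'   the stage classifier instead of using the generator's true trajectories
#'   (slow; default FALSE).
#' @param staging a [staging_settings()].
#' @param dvs character vector of subjective measures to model.
#' @param objective_measures character vector from `c("mvv", "ass")`.
#' @param cca_replications resampling replications for the Pillai-trace test.
#' @param output_dir where [run_pipeline()] writes its report bundle.
#' @param seed root seed for analysis-stage randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("simulate", "files"),
                            sim = sim_config(),
                            subject_table = NULL,
                            sequence_dir = NULL,
                            stage_recordings = FALSE,
                            staging = staging_settings(),
                            dvs = c("vas_pre", "ess_total", "kss_pre",
                                    "sss_pre", "asleep"),
                            objective_measures = c("mvv", "ass"),
                            cca_replications = 9999,
                            output_dir = tempfile("vigilr_run_"),
                            seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "files") {
    for (p in c(subject_table, sequence_dir)) {
      if (is.null(p) || !file.exists(p)) {
        abort("files mode requires existing `subject_table` and `sequence_dir`")
      }
    }
  }
  structure(
    list(input_mode = input_mode, sim = sim, subject_table = subject_table,
         sequence_dir = sequence_dir, stage_recordings = stage_recordings,
         staging = staging, dvs = dvs,
         objective_measures = objective_measures,
         cca_replications = cca_replications, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.metric_dvs <- c("vas_pre", "vas_post", "d_vas", "ess_total")

#' Run the full sleepiness analysis pipeline
#'
#' Orchestrates simulate (or load) -> stage -> summarize -> analyze ->
#' report.  In simulate mode the cohort generator supplies questionnaires
#' and vigilance trajectories; with `stage_recordings = TRUE` the EEG is
#' synthesized and re-staged by the classifier, otherwise the generator's
#' trajectories are summarized directly.  In files mode the subject table is
#' validated and scored, and per-subject stage sequences are read from disk
#' and summarized.
#'
#' The analysis battery comprises the four descriptive tables, the
#' group-wise objective-by-subjective Spearman correlation table, the
#' bootstrap Pillai-trace canonical correlation test, and the Gaussian /
#' proportional-odds interaction regressions for each requested dv and
#' objective measure.  All tables are written as CSV into `output_dir`
#' together with a JSON run manifest (configuration, seed, package version);
#' identical configurations and seeds yield byte-identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cohort and every result table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$input_mode == "simulate") {
    sim <- simulate_cohort(config$sim)
    cohort <- sim$cohort
    if (config$stage_recordings) {
      staged <- purrr::map2(sim$ground_truth$trajectory,
                            sim$ground_truth$seed, function(traj, sd) {
        rec <- synthesize_recording(traj, config$sim, seed = sd)
        stage_recording(rec, config$staging)
      })
      summaries <- dplyr::bind_rows(lapply(staged, arousal_summary))
      cohort[names(summaries)] <- summaries
    }
  } else {
    raw <- utils::read.csv(config$subject_table)
    cohort <- score_subject_table(raw)
    seq_paths <- file.path(config$sequence_dir,
                           paste0(cohort$id, ".tsv"))
    missing_seq <- !file.exists(seq_paths)
    if (any(missing_seq)) {
      abort(paste0("missing stage-sequence files for subject(s): ",
                   paste(cohort$id[missing_seq], collapse = ", ")))
    }
    summaries <- dplyr::bind_rows(
      lapply(seq_paths, function(p) arousal_summary(read_stage_sequence(p))))
    cohort <- dplyr::bind_cols(cohort, summaries)
  }

  bundle <- list(cohort = cohort)
  bundle$descriptives_metric <- describe_metric(cohort)
  bundle$descriptives_categorical <- describe_categorical(cohort)
  bundle$descriptives_ordinal <- describe_ordinal(cohort)
  bundle$descriptives_arousal <- describe_arousal(cohort)
  bundle$correlations <- correlation_table(cohort)

  cca <- cca_pillai_bootstrap(cohort,
                              replications = config$cca_replications,
                              seed = config$seed)
  bundle$cca <- glance(cca)
  bundle$cca_dimensions <- tidy(cca)

  models <- purrr::map_dfr(config$objective_measures, function(obj) {
    purrr::map_dfr(config$dvs, function(dv) {
      fam <- if (dv %in% .metric_dvs) "gaussian" else "proportional-odds"
      fit <- tryCatch(
        if (dv %in% .metric_dvs) {
          fit_linear_interaction_model(cohort, dv, obj)
        } else {
          fit_proportional_odds(cohort, dv, obj)
        },
        error = function(e) e)
      if (inherits(fit, "error")) {
        # record per-model failures (e.g. separation in a tiny subgroup)
        # instead of aborting the whole bundle
        return(tibble::tibble(dv = dv, objective = obj, family = fam,
                              term = NA_character_, df = NA_real_,
                              statistic = NA_real_, p_value = NA_real_,
                              note = conditionMessage(fit)))
      }
      dplyr::mutate(fit$tests, dv = dv, objective = obj, family = fam,
                    note = NA_character_, .before = 1)
    })
  })
  bundle$interaction_tests <- models

  for (nm in setdiff(names(bundle), "cohort")) {
    utils::write.csv(bundle[[nm]],
                     file.path(config$output_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort[setdiff(names(cohort),
                                  c(paste0("ess_", 1:8),
                                    paste0("rest_", 1:8)))],
                   file.path(config$output_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "vigilr",
    version = as.character(utils::packageVersion("vigilr")),
    input_mode = config$input_mode,
    seed = config$seed,
    cca_replications = config$cca_replications,
    dvs = config$dvs,
    objective_measures = config$objective_measures,
    group_sizes = as.list(config$sim$group_sizes),
    duration = config$sim$duration,
    sampling_rate = config$sim$sampling_rate,
    coupling = config$sim$coupling,
    sim_seed = config$sim$seed,
    multiplicity_correction = "none (by design; interpret p-values accordingly)"
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(bundle)
}
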