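#' Classify one second's features into a vigilance stage
#'
#' The decision cascade, applied in order:
#'
#' 1. spindle or K-complex flag -> `C` (sleep onset graphoelements dominate);
#' 2. scalp delta+theta power at least `b23_factor` times the recording
#'    baseline -> `B2/3`;
#' 3. alpha not predominant (`alpha_share <= alpha_share_min`): slow eye
#'    movements present -> `B1`, otherwise -> `0`;
#' 4. alpha predominant: `A1` / `A2` / `A3` by whether the occipital,
#'    temporal-parietal or frontal region carries the maximal alpha power.
#'
#' @param features one-row tibble from [extract_segment_features()].
#' @param baseline recording-level baseline delta+theta power
#'   (microvolt^2), e.g. from [stage_recording()].
#' @param settings a [staging_settings()].
#' @return a stage label string.
#' @export
classify_segment <- function(features, baseline,
                             settings = staging_settings()) {
  if (features$spindle || features$kcomplex) return("C")
  # the absolute floor keeps spectral leakage over a silent baseline from
  # counting as slow-wave elevation
  if (features$delta_theta >
        settings$b23_factor * max(baseline, settings$b23_min_power)) {
    return("B2/3")
  }
  if (features$alpha_share <= settings$alpha_share_min) {
    return(if (features$sem) "B1" else "0")
  }
  switch(features$alpha_topography,
         "occipital" = "A1",
         "temporal-parietal" = "A2",
         "frontal" = "A3")
}

#' Mask artifact-bearing seconds
#'
#' A second is masked if and only if any scalp channel's absolute amplitude
#' exceeds the threshold within it; EOG excursions never trigger the mask
#' (slow eye movements are signal, not artifact).
#'
#' @param recording an [eeg_recording()].
#' @param amplitude_threshold microvolts, > 0.
#' @return logical vector, one element per whole second.
#' @export
mask_artifacts <- function(recording, amplitude_threshold = 100) {
  if (amplitude_threshold <= 0) abort("amplitude_threshold must be > 0")
  fs <- as.integer(round(recording$sampling_rate))
  n_sec <- floor(ncol(recording$signal) / fs)
  scalp <- scalp_channels(recording)
  vapply(seq_len(n_sec), function(s) {
    idx <- ((s - 1L) * fs + 1L):(s * fs)
    any(abs(recording$signal[scalp, idx]) > amplitude_threshold)
  }, logical(1))
}

#' Stage a full recording at one-second resolution
#'
#' Masks artifacts, extracts per-second features, estimates the recording
#' baseline delta+theta power (the `baseline_quantile` of unmasked seconds),
#' and classifies every unmasked second by the [classify_segment()] cascade.
#' Masked seconds are labelled `ARTIFACT`.
#'
#' @param recording an [eeg_recording()] of at least 60 s (shorter
#'   recordings cannot support a stable baseline estimate).
#' @param settings a [staging_settings()].
#' @return a [stage_sequence()] with one label per whole second.
#' @export
stage_recording <- function(recording, settings = staging_settings()) {
  fs <- as.integer(round(recording$sampling_rate))
  n_sec <- floor(ncol(recording$signal) / fs)
  if (n_sec < 60) abort("recording must be at least 60 seconds long")
  mask <- mask_artifacts(recording, settings$artifact_threshold)
  feats <- dplyr::bind_rows(lapply(seq_len(n_sec), function(s) {
    extract_segment_features(recording, s, settings)
  }))
  if (!any(!mask)) abort("every second is masked as artifact")
  baseline <- unname(quantile(feats$delta_theta[!mask],
                              settings$baseline_quantile))
  stages <- rep("ARTIFACT", n_sec)
  for (s in which(!mask)) {
    stages[s] <- classify_segment(feats[s, ], baseline, settings)
  }
  stage_sequence(stages, artifact = mask)
}

#' Per-second agreement between two stage sequences
#'
#' Fraction of seconds that carry the same label, computed over seconds
#' unmasked in both sequences.  Used to validate the classifier against
#' generator ground truth.
#'
#' @param a,b stage sequences of equal length.
#' @return numeric fraction in \[0, 1\].
#' @export
staging_agreement <- function(a, b) {
  a <- as_stage_sequence(a); b <- as_stage_sequence(b)
  if (nrow(a) != nrow(b)) abort("sequences differ in length")
  keep <- !a$artifact & !b$artifact
  if (!any(keep)) abort("no jointly unmasked seconds")
  mean(a$stage[keep] == b$stage[keep])
}
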