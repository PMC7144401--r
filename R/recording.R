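#' Construct a multichannel EEG/EOG recording
#'
#' Container for a resting-state recording: a channels-by-samples signal
#' matrix in microvolts, the sampling rate, and a montage table mapping each
#' channel to a scalp region (`frontal`, `temporal-parietal`, `occipital`) or
#' to `eog`.  Every scalp region must be represented and exactly one EOG
#' channel is required.
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param montage data frame with columns `channel`, `region`; rows in signal
#'   order.
#' @param start_time optional informational time-of-day string.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, montage,
                          start_time = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric channels x samples matrix")
  }
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  montage <- tibble::as_tibble(montage)
  if (!all(c("channel", "region") %in% names(montage))) {
    abort("montage needs `channel` and `region` columns")
  }
  if (nrow(montage) != nrow(signal)) {
    abort("montage rows must match signal channels")
  }
  regions <- montage$region
  for (r in c("frontal", "temporal-parietal", "occipital")) {
    if (!any(regions == r)) abort(paste0("montage lacks a ", r, " channel"))
  }
  if (sum(regions == "eog") != 1L) {
    abort("montage must designate exactly one EOG channel")
  }
  rownames(signal) <- montage$channel
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         montage = montage, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.0f Hz, %.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat("channels:", paste(x$montage$channel, collapse = " "), "\n")
  invisible(x)
}

recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate
}

scalp_channels <- function(recording) {
  which(recording$montage$region != "eog")
}

eog_channel <- function(recording) {
  which(recording$montage$region == "eog")
}

#' Synthesize an EEG/EOG recording from a vigilance trajectory
#'
#' Realizes, second by second, the defining EEG characteristic of each
#' vigilance stage on a 10-20 montage (see [default_montage()]):
#'
#' * `0`: low-voltage broadband background only;
#' * `A1`/`A2`/`A3`: a 10 Hz alpha burst dominant over the occipital /
#'   temporal-parietal / frontal region respectively;
#' * `B1`: low-voltage background plus a slow (0.5 Hz half-cycle) horizontal
#'   deflection on the EOG channel;
#' * `B2/3`: added 2 Hz delta and 6 Hz theta components on all scalp
#'   channels;
#' * `C`: background plus a 1-second Hann-windowed 13.5 Hz spindle burst on
#'   the central channels, with an additional biphasic K-complex on the
#'   fronto-central channels in a random 30% of C seconds.
#'
#' Amplitudes come from `config$noise_scales` (microvolts).  Deterministic
#' given `seed`.
#'
#' @param trajectory a [stage_sequence()]; artifact seconds get background
#'   signal only.
#' @param config a [sim_config()] (supplies sampling rate and amplitudes).
#' @param seed integer seed.
#' @param montage montage table; default [default_montage()].
#' @return an [eeg_recording()].
#' @export
synthesize_recording <- function(trajectory, config, seed = 1L,
                                 montage = default_montage()) {
  stopifnot(inherits(config, "sim_config"))
  trajectory <- as_stage_sequence(trajectory)
  fs <- config$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    abort("sampling_rate must be an integer number of samples per second")
  }
  fs <- as.integer(round(fs))
  n_sec <- nrow(trajectory)
  ns <- config$noise_scales
  n_ch <- nrow(montage)
  scalp <- which(montage$region != "eog")
  eog <- which(montage$region == "eog")
  frontal <- which(montage$region == "frontal")
  tp <- which(montage$region == "temporal-parietal")
  occ <- which(montage$region == "occipital")
  central <- which(montage$channel %in% c("C3", "Cz", "C4"))
  if (length(central) == 0) central <- tp
  kc_ch <- which(montage$channel %in% c("Fz", "Cz", "C3", "C4"))
  if (length(kc_ch) == 0) kc_ch <- frontal

  set.seed(seed)
  x <- matrix(0, n_ch, n_sec * fs)
  # background: scalp Gaussian noise, quieter EOG baseline
  x[scalp, ] <- rnorm(length(scalp) * n_sec * fs, sd = ns$background)
  x[eog, ] <- rnorm(n_sec * fs, sd = ns$background / 2)

  tt <- (seq_len(fs) - 1) / fs
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(fs) / (fs + 1)))
  kc_len <- round(0.7 * fs)
  kc_template <- -sin(2 * pi * (seq_len(kc_len) - 1) / kc_len)

  for (s in seq_len(n_sec)) {
    stage <- trajectory$stage[s]
    idx <- ((s - 1L) * fs + 1L):(s * fs)
    if (stage %in% c("A1", "A2", "A3")) {
      dom <- switch(stage, A1 = occ, A2 = tp, A3 = frontal)
      amp <- rep(ns$alpha_other, n_ch)
      amp[dom] <- ns$alpha
      burst <- sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
      x[scalp, idx] <- x[scalp, idx] + outer(amp[scalp], burst)
    } else if (stage == "B1") {
      # slow horizontal eye movement: 0.5 Hz half-cycle on the EOG
      x[eog, idx] <- x[eog, idx] +
        sample(c(-1, 1), 1) * ns$sem * sin(pi * tt)
    } else if (stage == "B2/3") {
      slow <- ns$delta * sin(2 * pi * 2 * tt + runif(1, 0, 2 * pi)) +
        ns$theta * sin(2 * pi * 6 * tt + runif(1, 0, 2 * pi))
      x[scalp, idx] <- sweep(x[scalp, idx], 2, slow, `+`)
    } else if (stage == "C") {
      burst <- hann * sin(2 * pi * 13.5 * tt + runif(1, 0, 2 * pi))
      x[central, idx] <- x[central, idx] +
        matrix(rep(ns$spindle * burst, each = length(central)),
               nrow = length(central))
      if (runif(1) < 0.3) {
        off <- sample.int(fs - kc_len, 1)
        x[kc_ch, idx[off + seq_len(kc_len)]] <-
          x[kc_ch, idx[off + seq_len(kc_len)]] +
          matrix(rep(ns$kcomplex * kc_template, each = length(kc_ch)),
                 nrow = length(kc_ch))
      }
    }
    # stage "0" and ARTIFACT: background only
  }
  eeg_recording(x, fs, montage)
}

#' Write/read a recording as a delimited signal table
#'
#' Plain tab-separated text: a comment header line carrying the sampling
#' rate and one `channel:region` pair per channel, then one column per
#' channel, one row per sample, values in microvolts.
#'
#' @param recording an [eeg_recording()].
#' @param path file path.
#' @return `read_recording_table()` returns an [eeg_recording()];
#'   `write_recording_table()` returns `path` invisibly.
#' @export
write_recording_table <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate=%g %s", recording$sampling_rate,
                     paste(recording$montage$channel,
                           recording$montage$region,
                           sep = ":", collapse = " ")), con)
  utils::write.table(t(recording$signal), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = recording$montage$channel)
  invisible(path)
}

#' @rdname write_recording_table
#' @export
read_recording_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# sampling_rate=", header)) {
    abort("not a recording table: missing '# sampling_rate=' header")
  }
  fields <- strsplit(sub("^# ", "", header), " ")[[1]]
  fs <- as.numeric(sub("sampling_rate=", "", fields[1]))
  map <- strsplit(fields[-1], ":", fixed = TRUE)
  montage <- tibble::tibble(channel = vapply(map, `[`, "", 1),
                            region = vapply(map, `[`, "", 2))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs, montage)
}
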