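#' Staging settings
#'
#' All tunables of the vigilance classifier, with defaults chosen so that the
#' decision cascade reproduces each stage's defining characteristic exactly
#' on noiseless single-characteristic seconds:
#'
#' * `bands`: clinical band edges in Hz (delta 1-4, theta 4-8, alpha 8-12,
#'   total 1-30; spindle band 11-16);
#' * `alpha_share_min`: alpha is "predominant" when the scalp-wide alpha
#'   share of 1-30 Hz power exceeds this fraction (default 0.3);
#' * `b23_factor`: a second is B2/3 when its scalp delta+theta power exceeds
#'   `b23_factor` times the recording baseline (default 3; genuine
#'   slow-wave elevation is orders of magnitude above the low-quantile
#'   baseline, while periodogram noise fluctuates within roughly +-30% of
#'   it, so 3 clears the noise tail with a wide margin on both sides);
#' * `b23_min_power`: absolute floor (microvolt^2) on the delta+theta power
#'   that can count as slow-wave elevation, so that spectral leakage over a
#'   near-silent baseline is never read as B2/3 (default 1, i.e. a ~1.4
#'   microvolt component — far below any physiological slow wave);
#' * `baseline_quantile`: quantile of per-second delta+theta power over
#'   unmasked seconds used as the recording baseline (default 0.2; a low
#'   quantile keeps the baseline anchored to the non-elevated seconds even
#'   when drowsy B2/3 activity dominates the recording);
#' * `artifact_threshold`: absolute microvolt bound on scalp channels
#'   (default 100);
#' * `sem_threshold` / `sem_window`: peak-to-peak bound (microvolts) on the
#'   moving-average-smoothed EOG and the smoothing window in seconds
#'   (defaults 50 and 0.4; the 0.4 s boxcar has a spectral null at 2.5 Hz
#'   and passes <= 0.6 Hz deflections nearly unattenuated);
#' * `spindle_threshold`, `spindle_min_dur`, `spindle_rms_window`: 11-16 Hz
#'   envelope threshold (microvolts RMS), minimum supra-threshold run
#'   (seconds) and envelope smoothing window;
#' * `kcomplex_pp`, `kcomplex_corr`: peak-to-peak bound (microvolts) on the
#'   0.3-4 Hz filtered signal and minimum normalized correlation with the
#'   biphasic template.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class `staging_settings`.
#' @export
staging_settings <- function(...) {
  defaults <- list(
    bands = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                 total = c(1, 30), spindle = c(11, 16)),
    alpha_share_min = 0.3,
    b23_factor = 3,
    b23_min_power = 1,
    baseline_quantile = 0.2,
    artifact_threshold = 100,
    sem_threshold = 50,
    sem_window = 0.4,
    spindle_threshold = 6,
    spindle_min_dur = 0.5,
    spindle_max_dur = 2,
    spindle_rms_window = 0.25,
    kcomplex_pp = 75,
    kcomplex_corr = 0.6
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown staging settings: ", paste(unknown, collapse = ", ")))
  }
  structure(utils::modifyList(defaults, dots), class = "staging_settings")
}

# Hann-tapered periodogram band power of one channel-second, in microvolt^2
# (variance scale: a pure sinusoid of amplitude A yields ~A^2/2 summed over
# its band).  freq resolution is 1/len(x) * fs; bands are [lo, hi) in Hz.
band_powers <- function(x, fs, bands) {
  n <- length(x)
  h <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  h <- h / sqrt(mean(h^2))               # preserve variance scale
  xf <- fft((x - mean(x)) * h)
  nhalf <- floor(n / 2)
  pw <- (2 / n^2) * Mod(xf[2:(nhalf + 1)])^2
  freq <- (1:nhalf) * fs / n
  vapply(bands, function(b) sum(pw[freq >= b[1] & freq < b[2]]), 0)
}

#' Detect slow eye movements in an EOG segment
#'
#' Smooths the EOG with a moving-average (boxcar) low-pass whose window
#' (default 0.4 s) nulls activity at multiples of 2.5 Hz while passing slow
#' (<= 0.6 Hz) deflections nearly unattenuated, then flags the segment when
#' the peak-to-peak excursion of the smoothed interior exceeds the
#' threshold.
#'
#' @param eog_segment numeric vector, >= 1 s of EOG signal in microvolts.
#' @param sampling_rate Hz.
#' @param settings a [staging_settings()].
#' @return logical.
#' @export
detect_sem <- function(eog_segment, sampling_rate,
                       settings = staging_settings()) {
  if (length(eog_segment) < sampling_rate) {
    abort("EOG segment must be at least 1 second long")
  }
  w <- max(3L, round(settings$sem_window * sampling_rate))
  # reflection padding keeps the smoothed estimate defined over the whole
  # second, so deflections peaking near the segment edges are not clipped
  n <- length(eog_segment)
  pad <- min(w, n - 1L)
  x <- c(rev(eog_segment[seq_len(pad)]), eog_segment,
         rev(eog_segment[(n - pad + 1L):n]))
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm <- sm[pad + seq_len(n)]
  sm <- sm[!is.na(sm)]
  diff(range(sm)) > settings$sem_threshold
}

# exact band-pass via FFT bin masking (no filter transients on 1 s frames)
fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  xf <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided
  xf[freq < band[1] | freq > band[2]] <- 0
  Re(fft(xf, inverse = TRUE)) / n
}

sliding_rms <- function(x, w) {
  sq <- as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2))
  sqrt(pmax(sq, 0))
}

#' Detect a sleep-spindle burst in a scalp segment
#'
#' Band-passes each channel to 11-16 Hz (FFT bin masking), computes a
#' sliding-RMS envelope, and flags the segment when the envelope stays above
#' threshold for a run of `spindle_min_dur` to `spindle_max_dur` seconds on
#' any channel.
#'
#' @param segment numeric matrix, scalp channels x samples (>= 1 s).
#' @inheritParams detect_sem
#' @return logical.
#' @export
detect_spindle <- function(segment, sampling_rate,
                           settings = staging_settings()) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  w <- max(3L, round(settings$spindle_rms_window * sampling_rate))
  min_run <- round(settings$spindle_min_dur * sampling_rate)
  max_run <- round(settings$spindle_max_dur * sampling_rate)
  for (i in seq_len(nrow(segment))) {
    bp <- fft_bandpass(segment[i, ], sampling_rate, settings$bands$spindle)
    env <- sliding_rms(bp, w)
    above <- !is.na(env) & env > settings$spindle_threshold
    r <- rle(above)
    runs <- r$lengths[r$values]
    if (any(runs >= min_run & runs <= max_run)) return(TRUE)
  }
  FALSE
}

#' Detect a K-complex in a scalp segment
#'
#' Low-passes each channel to 0.3-4 Hz and flags the segment when the
#' filtered peak-to-peak excursion exceeds `kcomplex_pp` microvolts and the
#' maximal normalized cross-correlation with a biphasic (one-cycle sine,
#' 0.7 s) template exceeds `kcomplex_corr`.
#'
#' @inheritParams detect_spindle
#' @return logical.
#' @export
detect_kcomplex <- function(segment, sampling_rate,
                            settings = staging_settings()) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  kc_len <- round(0.7 * sampling_rate)
  template <- -sin(2 * pi * (seq_len(kc_len) - 1) / kc_len)
  template <- template / sqrt(sum(template^2))
  for (i in seq_len(nrow(segment))) {
    lp <- fft_bandpass(segment[i, ], sampling_rate, c(0.3, 4))
    if (diff(range(lp)) <= settings$kcomplex_pp) next
    n <- length(lp)
    best <- 0
    for (off in seq.int(0L, n - kc_len, by = max(1L, round(kc_len / 8)))) {
      win <- lp[off + seq_len(kc_len)]
      denom <- sqrt(sum(win^2))
      if (denom == 0) next
      cc <- abs(sum(win * template)) / denom
      if (cc > best) best <- cc
    }
    if (best > settings$kcomplex_corr) return(TRUE)
  }
  FALSE
}

#' Spectral and graphoelement features of one recording second
#'
#' Computes, for the 1-second segment starting at `second_index`, the
#' Hann-tapered periodogram band powers per scalp region (delta, theta,
#' alpha, 1-30 Hz total, in microvolt^2), the scalp-wide relative alpha
#' share, the region of maximal alpha power (ties broken occipital >
#' temporal-parietal > frontal, favouring the higher stage), the slow eye
#' movement, spindle and K-complex flags, and the peak absolute scalp
#' amplitude.
#'
#' @param recording an [eeg_recording()].
#' @param second_index 1-based second within the recording.
#' @param settings a [staging_settings()].
#' @return one-row tibble of features.
#' @export
extract_segment_features <- function(recording, second_index,
                                     settings = staging_settings()) {
  fs <- as.integer(round(recording$sampling_rate))
  n_sec <- floor(ncol(recording$signal) / fs)
  if (second_index < 1 || second_index > n_sec) {
    abort(sprintf("second_index must lie in 1..%d", n_sec))
  }
  idx <- ((second_index - 1L) * fs + 1L):(second_index * fs)
  if (length(idx) < fs) abort("segment shorter than 1 second")
  seg <- recording$signal[, idx, drop = FALSE]
  regions <- recording$montage$region
  scalp <- which(regions != "eog")
  bands <- settings$bands[c("delta", "theta", "alpha", "total")]

  pw <- t(vapply(scalp, function(i) band_powers(seg[i, ], fs, bands),
                 numeric(4)))
  colnames(pw) <- names(bands)
  region_order <- c("occipital", "temporal-parietal", "frontal")
  region_mean <- function(band) {
    vapply(region_order,
           function(r) mean(pw[regions[scalp] == r, band]), 0)
  }
  alpha_by_region <- region_mean("alpha")
  total_all <- sum(pw[, "total"])
  alpha_share <- if (total_all > 0) sum(pw[, "alpha"]) / total_all else 0
  # which.max takes the first maximum: region_order already encodes the
  # occipital > temporal-parietal > frontal tie-break
  alpha_topo <- region_order[which.max(alpha_by_region)]

  tibble::tibble(
    second = second_index,
    delta_frontal = region_mean("delta")[["frontal"]],
    delta_tp = region_mean("delta")[["temporal-parietal"]],
    delta_occipital = region_mean("delta")[["occipital"]],
    theta_frontal = region_mean("theta")[["frontal"]],
    theta_tp = region_mean("theta")[["temporal-parietal"]],
    theta_occipital = region_mean("theta")[["occipital"]],
    alpha_frontal = alpha_by_region[["frontal"]],
    alpha_tp = alpha_by_region[["temporal-parietal"]],
    alpha_occipital = alpha_by_region[["occipital"]],
    total_power = total_all / length(scalp),
    delta_theta = mean(pw[, "delta"] + pw[, "theta"]),
    alpha_share = alpha_share,
    alpha_topography = alpha_topo,
    sem = detect_sem(seg[eog_channel(recording), ], fs, settings),
    spindle = detect_spindle(seg[scalp, , drop = FALSE], fs, settings),
    kcomplex = detect_kcomplex(seg[scalp, , drop = FALSE], fs, settings),
    peak_amplitude = max(abs(seg[scalp, ]))
  )
}
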