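# Independent oracles and fixture builders shared across the suite.

# Brute-force arousal-stability rule table, coded independently of the
# package's precedence cascade: every score's criterion is evaluated as a
# standalone predicate and the *least stable* (minimum) applicable score is
# returned.  `stages_by_minute` is a character vector, one stage per scaled
# minute; minute m falls in bin min(m, 3).
oracle_ass <- function(stages_by_minute) {
  k <- length(stages_by_minute)
  bins <- pmin(seq_len(k), 3L)
  frac <- function(set) mean(stages_by_minute %in% set)
  first_bin <- function(set) {
    hit <- which(stages_by_minute %in% set)
    if (length(hit) == 0) NA_integer_ else bins[hit[1]]
  }
  applicable <- c(
    `1` = isTRUE(first_bin("C") == 1),
    `2` = isTRUE(first_bin("C") == 2),
    `3` = isTRUE(first_bin("C") == 3),
    `4` = frac("B2/3") >= 1 / 3 && isTRUE(first_bin("B2/3") == 1),
    `5` = frac("B2/3") >= 1 / 3 && isTRUE(first_bin("B2/3") == 2),
    `6` = frac("B2/3") >= 1 / 3 && isTRUE(first_bin("B2/3") == 3),
    `7` = frac(c("B1", "B2/3")) >= 1 / 3 &&
      isTRUE(first_bin(c("B1", "B2/3")) == 1),
    `8` = frac(c("B1", "B2/3")) >= 1 / 3 &&
      isTRUE(first_bin(c("B1", "B2/3")) == 2),
    `9` = frac(c("B1", "B2/3")) >= 1 / 3 &&
      isTRUE(first_bin(c("B1", "B2/3")) == 3),
    `10` = all(stages_by_minute %in% c("0", "A1", "A2", "A3")),
    `11` = all(stages_by_minute %in% c("0", "A1"))
  )
  # C beats B2/3 beats B; within a family the emergence bin is unique, so
  # the minimum applicable score is the cascade's answer
  if (any(applicable[1:3])) return(min(which(applicable[1:3])))
  if (any(applicable[4:6])) return(3L + min(which(applicable[4:6])))
  if (any(applicable[7:9])) return(6L + min(which(applicable[7:9])))
  if (applicable["11"]) return(11L)
  10L  # only-0/A rigidity, or B present below the one-third share
}

# A 20-minute (1200 s) sequence built from per-minute stage labels.
minutes_sequence <- function(stages_by_minute, seconds_per_minute = 60) {
  stage_sequence(rep(stages_by_minute, each = seconds_per_minute))
}

# Independent spectral oracle: raw periodogram band power (variance units)
# via stats::spec.pgram, no taper; band is [lo, hi) in Hz.
pgram_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  # spec.pgram returns density per unit frequency scaled so that
  # sum(spec) * df = var(x) / 2 is avoided by using its natural bins
  df <- sp$freq[2] - sp$freq[1]
  2 * sum(sp$spec[sp$freq >= band[1] & sp$freq < band[2]]) * df
}

# Hand-built single-second recording: a 13-channel montage whose scalp
# channels carry the given per-channel signal rows (list name -> vector).
tone_recording <- function(fs, n_sec, content = list()) {
  montage <- default_montage()
  n <- fs * n_sec
  sig <- matrix(0, nrow(montage), n)
  rownames(sig) <- montage$channel
  for (ch in names(content)) {
    sig[ch, ] <- content[[ch]]
  }
  eeg_recording(sig, fs, montage)
}

expect_stage_props <- function(sequence, expected) {
  p <- stage_proportions(sequence)
  expect_equal(unname(unlist(p)), expected, tolerance = 1e-12)
}
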