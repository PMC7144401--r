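# Minimal EDF (European Data Format) reader/writer: fixed-layout ASCII
# header (256 bytes + 256 per signal) followed by data records of 16-bit
# little-endian integers, linearly mapped between the digital and physical
# ranges declared per signal.  Covers continuous single-session recordings
# with a common sampling rate; annotations and discontinuous files are out
# of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @param record_duration seconds per data record (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_duration = 1) {
  sig <- recording$signal
  fs <- recording$sampling_rate
  spr <- as.integer(round(fs * record_duration))
  n_rec <- floor(ncol(sig) / spr)
  ns <- nrow(sig)
  phys_min <- floor(apply(sig, 1, min))
  phys_max <- ceiling(apply(sig, 1, max))
  phys_max <- pmax(phys_max, phys_min + 1)
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (ns + 1L), 8),
    .edf_pad("EDF", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(format(record_duration), 8),
    .edf_pad(ns, 4)
  )
  field <- function(values, width) {
    paste(vapply(values, .edf_pad, "", width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(recording$montage$channel, 16),
    field(rep("", ns), 80),                       # transducer
    field(rep("uV", ns), 8),                      # physical dimension
    field(format(phys_min), 8),
    field(format(phys_max), 8),
    field(rep(dig_min, ns), 8),
    field(rep(dig_max, ns), 8),
    field(rep("", ns), 80),                       # prefiltering
    field(rep(spr, ns), 8),
    field(rep("", ns), 32)                        # reserved
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      d <- round((sig[i, idx] - phys_min[i]) / scale[i]) + dig_min
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Signals are rescaled to their declared physical units; units other than
#' microvolts (`uV`) are converted when unambiguous (`mV`, `V`), otherwise
#' reading fails.  The montage region map is inferred from channel-name
#' prefixes unless `region_map` supplies explicit assignments.
#'
#' @param path EDF file path.
#' @param region_map optional named character vector `channel -> region`.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, region_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") abort("not an EDF file (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header length (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) {
    abort("mixed per-signal sampling rates are not supported")
  }
  unit_factor <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6,
           abort(paste0("ambiguous signal unit: '", d, "'")))
  }, 0)
  sig <- matrix(0, ns, n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                   endian = "little")
      sig[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (phys_min[i] + (d - dig_min[i]) * scale[i]) * unit_factor[i]
    }
  }
  montage <- tibble::tibble(channel = labels,
                            region = infer_regions(labels, region_map))
  eeg_recording(sig, spr[1] / rec_dur, montage)
}

#' Infer scalp regions from 10-20 channel names
#'
#' `Fp*`/`F*` map to frontal, `C*`/`T*`/`P*` to temporal-parietal, `O*` to
#' occipital, `EOG*` to eog; a `region_map` (named vector `channel ->
#' region`) overrides individual channels.  Unmappable channels fail with a
#' descriptive error.
#'
#' @param channels character vector of channel names.
#' @param region_map optional named character overrides.
#' @return character vector of regions.
#' @export
infer_regions <- function(channels, region_map = NULL) {
  out <- vapply(channels, function(ch) {
    if (!is.null(region_map) && ch %in% names(region_map)) {
      return(region_map[[ch]])
    }
    if (grepl("^EOG", ch, ignore.case = TRUE)) return("eog")
    if (grepl("^Fp|^F", ch)) return("frontal")
    if (grepl("^C|^T|^P", ch)) return("temporal-parietal")
    if (grepl("^O", ch)) return("occipital")
    abort(paste0("cannot infer a region for channel '", ch,
                 "'; supply a region_map"))
  }, "")
  valid <- c("frontal", "temporal-parietal", "occipital", "eog")
  bad <- !out %in% valid
  if (any(bad)) {
    abort(paste0("invalid region(s): ", paste(unique(out[bad]),
                                              collapse = ", ")))
  }
  unname(out)
}
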