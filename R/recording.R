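#' Continuous multichannel recording for one member of a dyad
#'
#' A `Recording` holds one subject's continuous EEG: a channels x samples
#' matrix in microvolts, sampled on a regular grid, with 10/20 channel
#' labels, the subject's role in the dyad (`"infant"` or `"adult"`), the
#' dyad identifier and the condition label. The online reference electrode
#' is carried as metadata (the acquisition montage in the emulated study
#' referenced to FCz).
#'
#' @param signal numeric matrix, channels x samples, microvolts
#' @param channels character vector of unique channel labels (rows of
#'   `signal`)
#' @param sampling_rate sampling rate in Hz
#' @param dyad_id dyad identifier
#' @param role `"infant"` or `"adult"`
#' @param condition condition label
#' @param reference_label reference electrode label (default `"FCz"`)
#' @return an object of class `Recording`
#' @export
new_recording <- function(signal, channels, sampling_rate, dyad_id, role,
                          condition, reference_label = "FCz") {
  signal <- as.matrix(signal)
  if (length(channels) != nrow(signal))
    stop("`channels` must have one label per signal row")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal contains NaN or non-finite values")
  if (!role %in% c("infant", "adult"))
    stop("role must be 'infant' or 'adult'")
  if (ncol(signal) < sampling_rate)
    stop("recording must be at least 1 s long")
  rownames(signal) <- channels
  structure(
    list(signal = signal, channels = as.character(channels),
         sampling_rate = sampling_rate, dyad_id = dyad_id, role = role,
         condition = condition, reference_label = reference_label),
    class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> dyad %s / %s / %s: %d ch x %.1f s @ %g Hz (ref %s)\n",
              x$dyad_id, x$role, x$condition, nrow(x$signal),
              ncol(x$signal) / x$sampling_rate, x$sampling_rate,
              x$reference_label))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording a `Recording`
#' @return duration in seconds
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate
}

# ---- columnar text format + JSON sidecar --------------------------------

#' Write a recording as TSV plus JSON sidecar
#'
#' The columnar text format is a TSV with header `time_s` followed by one
#' column per channel label, one row per sample; subject metadata (dyad id,
#' role, condition, sampling rate, reference) goes to `<path>.json`.
#'
#' @param recording a `Recording`
#' @param path output TSV path; the sidecar is written next to it
#' @return `path`, invisibly
#' @export
write_recording_tsv <- function(recording, path) {
  n <- ncol(recording$signal)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate,
                   t(recording$signal), check.names = FALSE)
  names(df) <- c("time_s", recording$channels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dyad_id = recording$dyad_id, role = recording$role,
               condition = recording$condition,
               sampling_rate = recording$sampling_rate,
               reference = recording$reference_label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording from TSV plus JSON sidecar
#'
#' @param path TSV path written by [write_recording_tsv()]
#' @return a `Recording`
#' @export
read_recording_tsv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  chans <- setdiff(names(df), "time_s")
  new_recording(t(as.matrix(df[chans])), chans, meta$sampling_rate,
                meta$dyad_id, meta$role, meta$condition,
                if (is.null(meta$reference)) "FCz" else meta$reference)
}

# ---- minimal EDF (16-bit European Data Format) --------------------------

edf_pad <- function(x, width) formatC(substr(x, 1, width), width = -width)

#' Write a recording to a 16-bit EDF file
#'
#' Single data record containing the whole signal, one EDF signal per
#' channel, physical range set from the data. Subject role/condition/dyad
#' are packed into the EDF local recording identification field.
#'
#' @param recording a `Recording`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_recording_edf <- function(recording, path) {
  sig <- recording$signal
  ns <- nrow(sig)
  nsamp <- ncol(sig)
  phys_min <- pmin(apply(sig, 1, min), -1)
  phys_max <- pmax(apply(sig, 1, max), 1)
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("X X X", recording$role), 80),
    edf_pad(paste("Startdate X", recording$dyad_id, recording$condition), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 + ns * 256), 8),
    edf_pad("", 44),
    edf_pad("1", 8),
    edf_pad(format(nsamp / recording$sampling_rate), 8),
    edf_pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(as.character(vals), edf_pad, "", width),
                     collapse = ""), con, eos = NULL)
  field(recording$channels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(format(phys_min, digits = 7), 8)
  field(format(phys_max, digits = 7), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(nsamp, ns), 8)
  field(rep("", ns), 32)                       # reserved
  for (ch in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[ch] - phys_min[ch])
    dig <- as.integer(round((sig[ch, ] - phys_min[ch]) * scale + dig_min))
    writeBin(pmin(pmax(dig, dig_min), dig_max), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file written by [write_recording_edf()]
#'
#' Standard EDF header parsing; supports multiple data records. The dyad id,
#' role and condition are recovered from the identification fields when
#' present (falling back to `"unknown"`).
#'
#' @param path EDF file path
#' @return a `Recording`
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                        # version
  patient <- rd(80)
  recid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8)); fld(32)
  out <- matrix(0, ns, sum(rep(nsamp[1], nrec)))
  for (r in seq_len(nrec)) for (ch in seq_len(ns)) {
    dig <- readBin(con, "integer", n = nsamp[ch], size = 2, signed = TRUE,
                   endian = "little")
    phys <- phys_min[ch] +
      (dig - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) /
        (dig_max[ch] - dig_min[ch])
    out[ch, (r - 1) * nsamp[ch] + seq_len(nsamp[ch])] <- phys
  }
  fs <- nsamp[1] / rec_dur
  ptoks <- strsplit(patient, " +")[[1]]
  rtoks <- strsplit(recid, " +")[[1]]
  role <- if (length(ptoks) >= 4 && ptoks[4] %in% c("infant", "adult"))
    ptoks[4] else "adult"
  dyad <- if (length(rtoks) >= 3) rtoks[3] else "unknown"
  cond <- if (length(rtoks) >= 4) rtoks[4] else "unknown"
  new_recording(out, labels, fs, dyad, role, cond)
}
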