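# File interchange: EDF, hypnogram/cue/event TSV, behavior CSV, WAV audio,
# JSON generator configs. EDF and WAV are written by hand here: both are
# fixed-layout binary formats (ASCII header + 16-bit little-endian samples).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write an EEG recording to EDF
#'
#' European Data Format, one data record per second, 16-bit samples scaled to
#' the physical range of each channel (microvolts).
#'
#' @param recording an `eeg_recording` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig <- recording$signal
  fs <- recording$fs
  stopifnot(fs == round(fs))
  nchan <- ncol(sig)
  spr <- as.integer(fs)             # samples per 1-s record
  nrec <- floor(nrow(sig) / spr)
  sig <- sig[seq_len(nrec * spr), , drop = FALSE]
  pmin_ <- vapply(seq_len(nchan), function(j) min(sig[, j], -1), 0)
  pmax_ <- vapply(seq_len(nchan), function(j) max(sig[, j], 1), 0)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nchan), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(1, 8), edf_pad(nchan, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(recording$channels, 16)
  field(rep("", nchan), 80)
  field(rep("uV", nchan), 8)
  field(formatC(pmin_, digits = 4, format = "f"), 8)
  field(formatC(pmax_, digits = 4, format = "f"), 8)
  field(rep(-32768, nchan), 8)
  field(rep(32767, nchan), 8)
  field(rep("", nchan), 80)
  field(rep(spr, nchan), 8)
  field(rep("", nchan), 32)

  scale <- (pmax_ - pmin_) / (32767 - (-32768))
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(nchan)) {
      dig <- round((sig[rows, j] - pmin_[j]) / scale[j]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an `eeg_recording`
#'
#' Supports the plain EDF layout this package writes (equal sampling rate on
#' every channel, 1-s data records).
#'
#' @param path EDF file path.
#' @param hypnogram optional stage vector to attach.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path, hypnogram = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  labels <- vapply(seq_len(nchan), function(i) rd(16), "")
  for (i in seq_len(nchan)) rd(80)
  for (i in seq_len(nchan)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  for (i in seq_len(nchan)) rd(80)
  spr <- as.integer(vapply(seq_len(nchan), function(i) rd(8), ""))
  for (i in seq_len(nchan)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / recdur
  out <- matrix(0, nrow = nrec * spr[1], ncol = nchan)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (j in seq_len(nchan)) {
      dig <- readBin(con, integer(), n = spr[j], size = 2,
                     endian = "little", signed = TRUE)
      out[rows, j] <- (dig - dmin[j]) * scale[j] + pmin_[j]
    }
  }
  colnames(out) <- labels
  eeg_recording(out, fs, labels, hypnogram = hypnogram)
}

#' Write / read a hypnogram TSV (one stage label per 30-s epoch)
#'
#' @param stages character vector of stage labels (W/N1/N2/N3/REM).
#' @param path file path.
#' @return for the reader, the stage vector; for the writer, `path` invisibly.
#' @export
write_hypnogram_tsv <- function(stages, path) {
  utils::write.table(data.frame(epoch = seq_along(stages), stage = stages),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_tsv
#' @export
read_hypnogram_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)$stage
}

#' Write / read a cue log TSV
#'
#' Columns: `onset_s`, `condition`, `phase_deg`, `online_valid`, `interval_id`.
#'
#' @param cues a `cue_log` or its `$cues` data frame.
#' @param path file path.
#' @return for the reader, a data frame; for the writer, `path` invisibly.
#' @export
write_cues_tsv <- function(cues, path) {
  if (inherits(cues, "cue_log")) cues <- cues$cues
  utils::write.table(cues[, c("onset_s", "condition", "phase_deg",
                              "online_valid", "interval_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cues_tsv
#' @export
read_cues_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write detected oscillatory events to TSV
#'
#' Columns: kind, channel, onset_s, offset_s, trough_uV, ptp_uV, freq_hz,
#' amp_uV.
#'
#' @param events data frame of events (`osc_events`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("kind", "channel", "onset_s", "offset_s", "trough_uV", "ptp_uV",
            "freq_hz", "amp_uV")
  for (cc in setdiff(cols, names(events))) events[[cc]] <- NA
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param wave numeric vector in `[-1, 1]`.
#' @param fs audio sampling rate (Hz).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path) {
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
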