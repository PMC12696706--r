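# Minimal EDF (European Data Format) writer/reader for recording exchange:
# 16-bit samples, one-second data records, event markers in a CSV sidecar
# (<file>.events.csv) rather than EDF+ annotation streams.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits against per-channel symmetric physical
#' ranges; the sampling rate must be a whole number (one-second records)
#' and trailing samples beyond the last whole second are dropped. Events
#' are written to `<file>.events.csv`.
#'
#' @param rec an [eeg_recording()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_edf <- function(rec, file) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmaxv <- pmax(apply(abs(x), 1, max), 1e-6) * 1.0001
  con <- file(file, "wb")
  on.exit(close(con))
  hdr_len <- 256L + 256L * nch
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(paste("synthetic subject", rec$condition), 80),
    pad_field("docbci export", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(hdr_len, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(nch, 4)),
    con, eos = NULL)
  fld <- function(get, width)
    writeChar(paste(vapply(seq_len(nch),
                           function(i) pad_field(get(i), width), ""),
                    collapse = ""), con, eos = NULL)
  fld(function(i) rec$channel_names[i], 16)
  fld(function(i) "", 80)
  fld(function(i) "uV", 8)
  fld(function(i) formatC(-pmaxv[i], digits = 5, format = "g"), 8)
  fld(function(i) formatC(pmaxv[i], digits = 5, format = "g"), 8)
  fld(function(i) "-32768", 8)
  fld(function(i) "32767", 8)
  fld(function(i) "", 80)
  fld(function(i) fs, 8)
  fld(function(i) "", 32)
  scale <- pmaxv / 32767
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round(x[ch, idx] / scale[ch]))
      writeBin(pmin(32767L, pmax(-32768L, dig)), con, size = 2,
               endian = "little")
    }
  }
  if (nrow(rec$events))
    write.csv(rec$events, paste0(file, ".events.csv"), row.names = FALSE)
  invisible(file)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param file path to the EDF file.
#' @param condition condition tag for the returned recording (also read
#'   from the patient field when present).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(file, condition = NULL) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_v <- as.numeric(rdv(8))
  pmax_v <- as.numeric(rdv(8))
  dmin_v <- as.numeric(rdv(8))
  dmax_v <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  fs <- spr[1] / rec_dur
  data <- matrix(0, nch, n_rec * spr[1])
  scale <- (pmax_v - pmin_v) / (dmax_v - dmin_v)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      data[ch, idx] <- (dig - dmin_v[ch]) * scale[ch] + pmin_v[ch]
    }
  }
  if (is.null(condition))
    condition <- if (grepl("task", patient)) "task" else "rest"
  ev_file <- paste0(file, ".events.csv")
  events <- if (file.exists(ev_file)) read.csv(ev_file) else NULL
  eeg_recording(data, fs, channel_names = labels, condition = condition,
                events = events)
}
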