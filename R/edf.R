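# Minimal EDF (European Data Format) support: ASCII header + 16-bit
# little-endian samples. Covers the plain continuous-EEG subset needed for
# reading polysomnography exports and round-tripping synthetic recordings;
# no EDF+ annotations, no per-signal sampling-rate mixtures.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's observed amplitude
#' range (per-channel physical min/max), so the round-trip error is at most
#' one quantization step.
#'
#' @param raw A [raw_recording()].
#' @param path Output path.
#' @param record_seconds Data-record duration (s); the recording length must
#'   be a whole number of records.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path, record_seconds = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sampling_rate
  spr <- round(fs * record_seconds)
  n_samp <- ncol(raw$signal)
  if (n_samp %% spr != 0) {
    stop("recording length must be a whole number of data records",
         call. = FALSE)
  }
  n_rec <- n_samp / spr
  ns <- nrow(raw$signal)

  pmin_ <- apply(raw$signal, 1, min)
  pmax_ <- apply(raw$signal, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_seconds), 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(raw$channel_labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), edf_pad, "", width = 8),
    vapply(sprintf("%.6g", pmax_), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((raw$signal[s, cols] - pmin_[s]) / scale[s] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A [raw_recording()] (all signals; they must share one sampling
#'   rate).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (length(ns) != 1 || is.na(ns) || ns < 1 || length(n_rec) != 1 ||
      is.na(n_rec)) {
    stop("not an EDF file: ", path, call. = FALSE)
  }
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("signals with mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[s] + (dig - dmin[s]) * (pmax_[s] - pmin_[s]) /
        (dmax[s] - dmin[s])
      sig[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  raw_recording(sig, fs, labels)
}
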