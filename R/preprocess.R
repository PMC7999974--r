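#' Common average reference
#'
#' Subtracts the instantaneous cross-channel mean from every channel,
#' suppressing noise common to the montage. Requires at least two channels.
#'
#' @param raw A [raw_recording()].
#' @return Re-referenced [raw_recording()].
#' @export
apply_car <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  if (nrow(raw$signal) < 2) {
    stop("common average reference needs >= 2 channels", call. = FALSE)
  }
  m <- colMeans(raw$signal)
  raw$signal <- sweep(raw$signal, 2, m)
  raw
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (zero phase lag), so
#' phase relations between channels are preserved.
#'
#' @param raw A [raw_recording()].
#' @param low_hz,high_hz Passband edges, `0 < low_hz < high_hz < fs/2`.
#' @return Filtered [raw_recording()].
#' @export
bandpass <- function(raw, low_hz, high_hz) {
  stopifnot(inherits(raw, "raw_recording"))
  flt <- butter_bandpass(low_hz, high_hz, raw$sampling_rate)
  raw$signal <- t(apply(raw$signal, 1, function(ch) filt_zero_phase(flt, ch)))
  raw
}

#' Curate a hypnogram: drop unreliable stage labels
#'
#' Applies three deletion rules, in order, before epochs are cut:
#' \enumerate{
#'   \item whole stage runs shorter than `min_run_epochs` are dropped
#'     (too-short bouts whose labels are unreliable); short wake runs that
#'     qualify as intrusions under rule 2 are left for rule 2;
#'   \item wake (`W`) runs of at most `intrusion_max_epochs` epochs flanked
#'     by sleep on both sides are dropped together with one epoch before and
#'     one after; fragments this creates are re-checked against
#'     `min_run_epochs`;
#'   \item the first and last epoch of each surviving run are trimmed
#'     (stage-transition boundaries).
#' }
#' Finally only REM/N2/N3 epochs are returned.
#'
#' @param hyp Character vector of stage labels (one per 30 s epoch), from
#'   `{W, REM, N1, N2, N3}`.
#' @param min_run_epochs Minimum run length kept, in epochs (default 6 = 3
#'   minutes).
#' @param intrusion_max_epochs Longest W run treated as an intrusion
#'   (default 2 epochs = 1 minute).
#' @return Sorted integer vector of kept epoch indices (1-based); may be
#'   empty.
#' @export
curate_hypnogram <- function(hyp, min_run_epochs = 6,
                             intrusion_max_epochs = 2) {
  if (length(hyp) == 0) stop("empty hypnogram", call. = FALSE)
  hyp <- as.character(hyp)
  n <- length(hyp)
  keep <- rep(TRUE, n)

  r <- rle(hyp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)

  is_intrusion <- rep(FALSE, k)
  for (i in seq_len(k)) {
    if (r$values[i] == "W" && r$lengths[i] <= intrusion_max_epochs &&
        i > 1 && i < k && r$values[i - 1] != "W" && r$values[i + 1] != "W") {
      is_intrusion[i] <- TRUE
    }
  }

  # rule 1: short runs out (intrusions deferred to rule 2)
  for (i in seq_len(k)) {
    if (r$lengths[i] < min_run_epochs && !is_intrusion[i]) {
      keep[starts[i]:ends[i]] <- FALSE
    }
  }

  # rule 2: intrusions out, plus one flanking epoch each side
  for (i in which(is_intrusion)) {
    lo <- max(1, starts[i] - 1)
    hi <- min(n, ends[i] + 1)
    keep[lo:hi] <- FALSE
  }

  # re-check fragments against the run-length minimum, then trim boundaries
  frag <- fragment_runs(hyp, keep)
  for (f in frag) {
    if (length(f) < min_run_epochs) keep[f] <- FALSE
  }
  frag <- fragment_runs(hyp, keep)
  for (f in frag) {
    keep[f[1]] <- FALSE
    keep[f[length(f)]] <- FALSE
  }

  idx <- which(keep & hyp %in% stage_levels())
  sort(idx)
}

# maximal contiguous index segments with a constant stage among kept epochs
fragment_runs <- function(hyp, keep) {
  idx <- which(keep)
  if (!length(idx)) return(list())
  brk <- c(TRUE, diff(idx) != 1 | hyp[idx[-1]] != hyp[idx[-length(idx)]])
  split(idx, cumsum(brk))
}

#' Cut a recording into labelled 30 s epochs
#'
#' Epoch `i` (1-based) covers samples `[(i-1)*30*fs, i*30*fs)` of the
#' recording -- non-overlapping, aligned to the hypnogram.
#'
#' @param raw A [raw_recording()].
#' @param hyp Stage labels, one per epoch.
#' @param kept Integer indices of epochs to extract (e.g. from
#'   [curate_hypnogram()]).
#' @param epoch_seconds Epoch duration (s).
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(raw, hyp, kept, epoch_seconds = 30) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sampling_rate
  spe <- round(fs * epoch_seconds)
  n_total <- ncol(raw$signal)
  kept <- sort(as.integer(kept))
  if (length(kept) && (min(kept) < 1 || max(kept) * spe > n_total)) {
    stop("kept epoch index beyond recording length", call. = FALSE)
  }
  if (length(kept) && max(kept) > length(hyp)) {
    stop("kept epoch index beyond hypnogram length", call. = FALSE)
  }
  data <- array(0, dim = c(length(kept), nrow(raw$signal), spe))
  for (j in seq_along(kept)) {
    i <- kept[j]
    data[j, , ] <- raw$signal[, ((i - 1) * spe + 1):(i * spe)]
  }
  epoch_set(data, hyp[kept], fs, channel_labels = raw$channel_labels)
}

#' Decompose epochs into the six-band filter bank
#'
#' Applies the zero-phase band-pass independently per epoch and channel for
#' each band, preserving epoch order and labels.
#'
#' @param epochs An [epoch_set()] (already broadband-filtered).
#' @param bands Band-definition tibble; defaults to [eeg_bands()].
#' @return Named list of [epoch_set()], one per band.
#' @export
filter_bank <- function(epochs, bands = eeg_bands()) {
  stopifnot(inherits(epochs, "epoch_set"))
  validate_bands(bands)
  fs <- epochs$sampling_rate
  out <- list()
  for (b in seq_len(nrow(bands))) {
    flt <- butter_bandpass(bands$low_hz[b], bands$high_hz[b], fs)
    data <- epochs$data
    if (dim(data)[1] > 0) {
      for (i in seq_len(dim(data)[1])) {
        for (ch in seq_len(dim(data)[2])) {
          data[i, ch, ] <- filt_zero_phase(flt, data[i, ch, ])
        }
      }
    }
    out[[as.character(bands$band[b])]] <-
      epoch_set(data, epochs$labels, fs, band = as.character(bands$band[b]),
                channel_labels = epochs$channel_labels)
  }
  out
}

#' Amplitude-based epoch rejection
#'
#' Optional stand-in for component-based artifact removal: flags epochs whose
#' peak absolute amplitude exceeds a threshold. Disabled when
#' `threshold_uv` is `NULL` or infinite.
#'
#' @param epochs An [epoch_set()].
#' @param threshold_uv Peak amplitude threshold in microvolts.
#' @return Logical vector, `TRUE` for epochs to keep.
#' @export
reject_amplitude <- function(epochs, threshold_uv = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(threshold_uv) || !is.finite(threshold_uv)) {
    return(rep(TRUE, length(epochs)))
  }
  apply(epochs$data, 1, function(e) max(abs(e)) <= threshold_uv)
}

#' Read a plain-text hypnogram file
#'
#' Two dialects are supported: one stage label per line, or two whitespace-
#' or comma-separated columns `(onset_seconds, stage)` where onsets are
#' multiples of the epoch length.
#'
#' @param path File path.
#' @param epoch_seconds Epoch duration for the two-column dialect.
#' @return Character vector of stage labels, one per epoch. `S3`/`S4` labels
#'   are mapped to `N3`; `S1`/`S2` to `N1`/`N2`; `R` to `REM`.
#' @export
read_hypnogram <- function(path, epoch_seconds = 30) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty hypnogram file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[,\t ]+")
  ncols <- lengths(parts)
  if (all(ncols == 1)) {
    stages <- vapply(parts, `[[`, "", 1)
  } else if (all(ncols == 2)) {
    onset <- as.numeric(vapply(parts, `[[`, "", 1))
    stages <- vapply(parts, `[[`, "", 2)
    ord <- order(onset)
    onset <- onset[ord]; stages <- stages[ord]
    if (any(abs(onset / epoch_seconds - round(onset / epoch_seconds)) >
            1e-6)) {
      stop("onsets must be multiples of the epoch length", call. = FALSE)
    }
    idx <- round(onset / epoch_seconds) + 1
    out <- rep(NA_character_, max(idx))
    out[idx] <- stages
    if (anyNA(out)) stop("hypnogram has gaps", call. = FALSE)
    stages <- out
  } else {
    stop("unrecognized hypnogram format: ", path, call. = FALSE)
  }
  map <- c(S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3", R = "REM",
           W = "W", REM = "REM", N1 = "N1", N2 = "N2", N3 = "N3")
  out <- unname(map[toupper(stages)])
  if (anyNA(out)) {
    stop("unknown stage labels: ",
         paste(unique(stages[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
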