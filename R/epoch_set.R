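#' Stage-labelled multichannel EEG epochs
#'
#' Container for a set of non-overlapping 30 s (or other fixed-length)
#' analysis windows. Signals live in an `epochs x channels x samples` array;
#' labels, sampling rate and (optionally) the band the data were filtered to
#' ride along as attributes. Everything downstream of PLV extraction is
#' tabular; this is the one deliberately array-shaped object in the package.
#'
#' @param data Numeric array, `epochs x channels x samples` (microvolts).
#' @param labels Character or factor, one sleep-stage label per epoch.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Optional band name if the data are narrowband-filtered.
#' @param channel_labels Optional character vector of channel names.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate, band = NULL,
                      channel_labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_epochs <- dim(data)[1L]
  if (length(labels) != n_epochs) {
    stop("need one label per epoch", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  }
  structure(
    list(
      data = data,
      labels = as.character(labels),
      sampling_rate = sampling_rate,
      band = band,
      channel_labels = channel_labels
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz%s\n",
    d[1], d[2], d[3], x$sampling_rate,
    if (is.null(x$band)) "" else paste0(" [", x$band, "]")
  ))
  if (d[1] > 0) {
    tab <- table(x$labels)
    cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.epoch_set <- function(x) dim(x$data)[1L]

n_channels <- function(x) dim(x$data)[2L]
n_samples <- function(x) dim(x$data)[3L]

#' Epoch labels as a tibble
#'
#' @param x An [epoch_set()].
#' @param ... Unused.
#' @return Tibble with columns `epoch` and `stage`.
#' @export
epoch_labels <- function(x, ...) {
  tibble::tibble(epoch = seq_len(length(x)), stage = x$labels)
}

#' Raw recording container
#'
#' A continuous multichannel recording: `channels x samples` matrix plus the
#' sampling rate and channel (derivation) labels.
#'
#' @param signal Numeric matrix, channels in rows.
#' @param sampling_rate Hz.
#' @param channel_labels Character vector, one per channel.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sampling_rate, channel_labels = NULL) {
  stopifnot(is.matrix(signal), sampling_rate > 0)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  stopifnot(length(channel_labels) == nrow(signal))
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_labels = channel_labels),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  invisible(x)
}
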