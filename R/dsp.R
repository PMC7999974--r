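# Shared signal-processing primitives: zero-phase Butterworth filtering and
# the FFT analytic signal. Filtering is forward-backward (signal::filtfilt)
# so band-pass steps add no phase distortion -- a hard requirement here, since
# everything downstream is a phase statistic.

butter_bandpass <- function(low_hz, high_hz, fs, order = 4) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band edges must satisfy 0 < %g < %g < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq), call. = FALSE)
  }
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

filt_zero_phase <- function(flt, x) {
  signal::filtfilt(flt, x)
}

#' Analytic signal via the FFT
#'
#' Complex extension of a real signal whose argument is the instantaneous
#' phase and whose modulus is the instantaneous amplitude.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("signal too short for analytic transform", call. = FALSE)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
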