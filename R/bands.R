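#' Canonical EEG frequency bands
#'
#' The six narrowband ranges used throughout the pipeline, in fixed
#' low-to-high order: delta (0.5--4 Hz), theta (4--8 Hz), alpha (8--13 Hz),
#' beta1 (13--22 Hz), beta2 (22--30 Hz), gamma (30--40 Hz).
#'
#' @return A tibble with columns `band` (factor, canonical order),
#'   `low_hz`, `high_hz`.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = factor(band_order(), levels = band_order()),
    low_hz  = c(0.5, 4, 8, 13, 22, 30),
    high_hz = c(4, 8, 13, 22, 30, 40)
  )
}

#' Canonical band ordering
#'
#' @return Character vector of the six band names, low to high frequency.
#' @export
band_order <- function() {
  c("delta", "theta", "alpha", "beta1", "beta2", "gamma")
}

#' Sleep stages retained for analysis
#'
#' @return Character vector `c("REM", "N2", "N3")`.
#' @export
stage_levels <- function() {
  c("REM", "N2", "N3")
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("band", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$low_hz >= bands$high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  invisible(bands)
}
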