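#' Expected PLV of a wrapped-normal phase error
#'
#' Closed-form calibration target for the synthetic generator. If the phase
#' difference between two signals is wrapped-normal with standard deviation
#' `sigma` (radians), the phase-locking value converges to
#' `exp(-sigma^2 / 2)` -- the modulus of the wrapped-normal characteristic
#' function at harmonic 1.
#'
#' @param sigma Phase-jitter standard deviation in radians (vectorised,
#'   all values `>= 0`).
#' @return Expected PLV in `(0, 1]`.
#' @examples
#' plv_target_from_sigma(c(0, 1))  # 1, exp(-0.5)
#' @export
plv_target_from_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(is.na(sigma)) || any(sigma < 0)) {
    stop("sigma must be non-negative", call. = FALSE)
  }
  exp(-sigma^2 / 2)
}

#' Phase-jitter standard deviation achieving a target PLV
#'
#' Inverse of [plv_target_from_sigma()].
#'
#' @param plv Target PLV in `(0, 1]`.
#' @return Sigma in radians.
#' @export
sigma_from_plv <- function(plv) {
  if (!is.numeric(plv) || any(is.na(plv)) || any(plv <= 0) || any(plv > 1)) {
    stop("plv must lie in (0, 1]", call. = FALSE)
  }
  sqrt(-2 * log(plv))
}

#' Stage- and band-specific coupling specification
#'
#' One row of the generator's coupling table: for a given (stage, band) pair,
#' how strongly channel pairs are phase-coupled, how loud the band carrier is
#' and how much broadband noise is added.
#'
#' @param stage Stage label (`"REM"`, `"N2"`, `"N3"`).
#' @param band Band name (see [band_order()]).
#' @param pair_sigma Pairwise phase-jitter sd in radians: a scalar (uniform
#'   across channel pairs) or a symmetric `C x C` matrix.
#' @param band_amplitude Relative carrier amplitude (dimensionless).
#' @param noise_amplitude Broadband white-noise scale (dimensionless).
#' @return One-row tibble.
#' @export
coupling_spec <- function(stage, band, pair_sigma, band_amplitude = 1,
                          noise_amplitude = 0.3) {
  stopifnot(length(stage) == 1, length(band) == 1)
  if (is.matrix(pair_sigma)) {
    if (nrow(pair_sigma) != ncol(pair_sigma) ||
        any(abs(pair_sigma - t(pair_sigma)) > 1e-12)) {
      stop("pair_sigma matrix must be square symmetric", call. = FALSE)
    }
    if (any(pair_sigma < 0)) stop("pair_sigma must be >= 0", call. = FALSE)
  } else {
    stopifnot(is.numeric(pair_sigma), length(pair_sigma) == 1)
    if (pair_sigma < 0) stop("pair_sigma must be >= 0", call. = FALSE)
  }
  tibble::tibble(
    stage = as.character(stage), band = as.character(band),
    pair_sigma = list(pair_sigma),
    band_amplitude = band_amplitude, noise_amplitude = noise_amplitude
  )
}

#' Default stage-by-band coupling table
#'
#' The generator's standard study conditions: uniform pairwise PLV targets
#' per (stage, band) chosen so that mean PLV decreases from delta to gamma,
#' increases from N2 to N3 in the delta and alpha bands, and decreases from
#' N2 to N3 in the beta2 and gamma bands. Carrier amplitudes fall off with
#' frequency, mimicking the 1/f shape of EEG spectra.
#'
#' @param noise_amplitude Broadband noise scale shared by all rows.
#' @return Coupling tibble (18 rows: 3 stages x 6 bands).
#' @export
default_coupling <- function(noise_amplitude = 0.3) {
  targets <- tibble::tribble(
    ~band,    ~REM, ~N2,  ~N3,
    "delta",  0.55, 0.60, 0.75,
    "theta",  0.45, 0.50, 0.55,
    "alpha",  0.50, 0.55, 0.70,
    "beta1",  0.45, 0.45, 0.40,
    "beta2",  0.35, 0.40, 0.28,
    "gamma",  0.30, 0.35, 0.22
  )
  amps <- c(delta = 1.0, theta = 0.8, alpha = 0.7,
            beta1 = 0.5, beta2 = 0.4, gamma = 0.3)
  long <- tidyr::pivot_longer(targets, -"band", names_to = "stage",
                              values_to = "plv")
  purrr::pmap_dfr(long, function(band, stage, plv) {
    coupling_spec(stage, band, sigma_from_plv(plv),
                  band_amplitude = unname(amps[band]),
                  noise_amplitude = noise_amplitude)
  })
}

coupling_from_plv_table <- function(targets, amps = NULL,
                                    noise_amplitude = 0.3) {
  if (is.null(amps)) {
    amps <- c(delta = 1.0, theta = 0.8, alpha = 0.7,
              beta1 = 0.5, beta2 = 0.4, gamma = 0.3)
  }
  long <- tidyr::pivot_longer(targets, -"band", names_to = "stage",
                              values_to = "plv")
  purrr::pmap_dfr(long, function(band, stage, plv) {
    coupling_spec(stage, band, sigma_from_plv(plv),
                  band_amplitude = unname(amps[band]),
                  noise_amplitude = noise_amplitude)
  })
}

#' Coupling preset: contrast planted in a single band
#'
#' All bands carry signal, but only `band` has stage-dependent coupling;
#' every other band keeps a flat PLV across stages. Used to test that the
#' band-ranking statistics recover the informative band.
#'
#' @param band Band receiving the stage contrast.
#' @param plv_by_stage Named numeric (REM, N2, N3) PLV targets in `band`.
#' @param flat_plv PLV of all other bands in every stage.
#' @param noise_amplitude Broadband noise scale.
#' @return Coupling tibble.
#' @export
coupling_band_contrast <- function(band = "alpha",
                                   plv_by_stage = c(REM = 0.35, N2 = 0.55,
                                                    N3 = 0.75),
                                   flat_plv = 0.45, noise_amplitude = 0.3) {
  stopifnot(band %in% band_order(),
            all(stage_levels() %in% names(plv_by_stage)))
  hit <- band_order() == band
  targets <- tibble::tibble(
    band = band_order(),
    REM = ifelse(hit, plv_by_stage[["REM"]], flat_plv),
    N2  = ifelse(hit, plv_by_stage[["N2"]], flat_plv),
    N3  = ifelse(hit, plv_by_stage[["N3"]], flat_plv)
  )
  coupling_from_plv_table(targets, noise_amplitude = noise_amplitude)
}

#' Coupling preset: no stage contrast
#'
#' Identical coupling in every stage: downstream classifiers should sit at
#' chance, band rankings should be noise.
#'
#' @param flat_plv Uniform PLV target for every (stage, band).
#' @param noise_amplitude Broadband noise scale.
#' @return Coupling tibble.
#' @export
coupling_zero_contrast <- function(flat_plv = 0.45, noise_amplitude = 0.3) {
  targets <- tibble::tibble(band = band_order(), REM = flat_plv,
                            N2 = flat_plv, N3 = flat_plv)
  coupling_from_plv_table(targets, noise_amplitude = noise_amplitude)
}

#' Coupling preset: complementary bands
#'
#' Each of three bands singles out one stage (its PLV drops only in that
#' stage), so no single band can separate all three classes but their
#' combination can. Used for the fusion-dominance experiments.
#'
#' @param lo,hi Low/high PLV levels defining the one-vs-rest contrast.
#' @param flat_plv PLV of the three uninformative bands.
#' @param noise_amplitude Broadband noise scale.
#' @return Coupling tibble.
#' @export
coupling_complementary <- function(lo = 0.30, hi = 0.65, flat_plv = 0.45,
                                   noise_amplitude = 0.3) {
  targets <- tibble::tribble(
    ~band,    ~REM,     ~N2,      ~N3,
    "delta",  lo,       hi,       hi,        # drops only in REM
    "theta",  flat_plv, flat_plv, flat_plv,
    "alpha",  hi,       lo,       hi,        # drops only in N2
    "beta1",  flat_plv, flat_plv, flat_plv,
    "beta2",  hi,       hi,       lo,        # drops only in N3
    "gamma",  flat_plv, flat_plv, flat_plv
  )
  coupling_from_plv_table(targets, noise_amplitude = noise_amplitude)
}

#' Coupling preset: single active band for calibration
#'
#' Only `band` carries a carrier (uniform pairwise jitter `sigma`); the other
#' five bands have zero amplitude and the broadband noise floor is small, so
#' the measured PLV in `band` can be compared to the closed-form target
#' [plv_target_from_sigma()].
#'
#' @param sigma Uniform pairwise phase-jitter sd (radians).
#' @param band The active band.
#' @param noise_amplitude Small broadband noise scale.
#' @param stages Stages to populate (calibration needs just one).
#' @return Coupling tibble.
#' @export
coupling_calibration <- function(sigma, band = "alpha",
                                 noise_amplitude = 0.05,
                                 stages = "N2") {
  purrr::map_dfr(stages, function(st) {
    purrr::map_dfr(band_order(), function(b) {
      coupling_spec(st, b,
                    pair_sigma = if (b == band) sigma else 0,
                    band_amplitude = if (b == band) 1 else 0,
                    noise_amplitude = noise_amplitude)
    })
  })
}

#' Generator configuration
#'
#' Bundles everything [synth_dataset()] needs. Defaults match the recording
#' geometry the pipeline targets: 12 bipolar channels at 512 Hz in 30 s
#' epochs.
#'
#' @param n_channels Number of channels (`>= 2`).
#' @param sampling_rate Hz.
#' @param epoch_seconds Epoch duration (s).
#' @param epochs_per_stage Epochs generated per stage (`>= 1`).
#' @param seed Master seed; per-epoch child seeds are derived from it.
#' @param coupling Coupling tibble covering every (stage, band); see
#'   [default_coupling()] and the `coupling_*` presets.
#' @param stages Stage labels to generate.
#' @param jitter_bandwidth_hz Bandwidth of the slowly varying phase jitter.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_channels = 12, sampling_rate = 512,
                             epoch_seconds = 30, epochs_per_stage = 20,
                             seed = 1, coupling = default_coupling(),
                             stages = stage_levels(),
                             jitter_bandwidth_hz = 1) {
  stopifnot(n_channels >= 2, epochs_per_stage >= 1, sampling_rate > 0,
            epoch_seconds > 0)
  missing <- setdiff(
    paste(rep(stages, each = 6), band_order()),
    paste(coupling$stage, coupling$band)
  )
  if (length(missing)) {
    stop("coupling table missing (stage, band) combinations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste(coupling$stage, coupling$band))
  if (any(dup)) stop("duplicate (stage, band) coupling rows", call. = FALSE)
  structure(
    list(n_channels = n_channels, sampling_rate = sampling_rate,
         epoch_seconds = epoch_seconds, epochs_per_stage = epochs_per_stage,
         seed = seed, coupling = coupling, stages = stages,
         jitter_bandwidth_hz = jitter_bandwidth_hz),
    class = "generator_config"
  )
}

# Per-channel jitter variances realizing a pairwise sigma matrix under the
# shared-carrier convention sigma_pair^2 = sigma_i^2 + sigma_j^2.
# Least-squares closed form; exact when the matrix is additively consistent
# (always for a uniform matrix: each channel gets sigma/sqrt(2)).
channel_sigmas <- function(pair_sigma, n_channels) {
  if (!is.matrix(pair_sigma)) {
    return(rep(pair_sigma / sqrt(2), n_channels))
  }
  C <- n_channels
  stopifnot(nrow(pair_sigma) == C)
  S2 <- pair_sigma^2
  diag(S2) <- 0
  R <- rowSums(S2)
  if (C == 2) {
    v <- rep(R[1] / 2, 2)
  } else {
    V <- sum(R) / (2 * C - 2)
    v <- (R - V) / (C - 2)
  }
  sqrt(pmax(v, 0))
}

# Slowly varying Gaussian phase jitter with exact marginal sd.
phase_jitter <- function(n, sd_target, fs, bandwidth_hz) {
  if (sd_target <= 0) return(numeric(n))
  lp <- signal::butter(2, bandwidth_hz / (fs / 2), type = "low")
  th <- filt_zero_phase(lp, rnorm(n))
  th / sd(th) * sd_target
}

#' Generate one synthetic epoch
#'
#' Per band, a shared narrowband carrier (band-pass filtered Gaussian noise)
#' is distributed to all channels; each channel perturbs the carrier's
#' instantaneous phase with an independent, slowly varying wrapped-normal
#' jitter whose sd realizes the configured pairwise coupling. Channel signal
#' is the amplitude-weighted sum over bands plus white noise. Deterministic
#' given `epoch_seed`.
#'
#' @param stage Stage label with coupling rows in `config`.
#' @param config A [generator_config()].
#' @param epoch_seed Integer seed for this epoch.
#' @return `channels x samples` numeric matrix.
#' @export
synth_epoch <- function(stage, config, epoch_seed) {
  stopifnot(inherits(config, "generator_config"))
  spec <- dplyr::filter(config$coupling, .data$stage == !!stage)
  if (nrow(spec) == 0) stop("unknown stage label: ", stage, call. = FALSE)
  fs <- config$sampling_rate
  n <- round(fs * config$epoch_seconds)
  C <- config$n_channels
  bands <- eeg_bands()
  set.seed(epoch_seed)
  x <- matrix(0, nrow = C, ncol = n)
  for (b in seq_len(nrow(bands))) {
    row <- spec[spec$band == as.character(bands$band[b]), ]
    amp_b <- row$band_amplitude[[1]]
    sig <- row$pair_sigma[[1]]
    if (amp_b == 0) next
    bp <- butter_bandpass(bands$low_hz[b], bands$high_hz[b], fs)
    carrier <- filt_zero_phase(bp, rnorm(n))
    za <- analytic_signal(carrier)
    a <- Mod(za) / stats::sd(carrier)   # unit-RMS carrier envelope
    ph <- Arg(za)
    sds <- channel_sigmas(sig, C)
    for (ch in seq_len(C)) {
      th <- phase_jitter(n, sds[ch], fs, config$jitter_bandwidth_hz)
      x[ch, ] <- x[ch, ] + amp_b * Re(a * exp(1i * (ph + th)))
    }
  }
  noise <- mean(spec$noise_amplitude)
  if (noise > 0) {
    x <- x + noise * matrix(rnorm(C * n), nrow = C)
  }
  x
}

#' Generate a stage-labelled synthetic dataset
#'
#' `epochs_per_stage` epochs per stage under the configured coupling,
#' shuffled with a seeded permutation. Identical `config` (including seed)
#' reproduces the dataset bit for bit.
#'
#' @param config A [generator_config()].
#' @return An [epoch_set()].
#' @export
synth_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  stages <- rep(config$stages, each = config$epochs_per_stage)
  n_ep <- length(stages)
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max, n_ep)
  perm <- sample.int(n_ep)
  fs <- config$sampling_rate
  n <- round(fs * config$epoch_seconds)
  data <- array(0, dim = c(n_ep, config$n_channels, n))
  for (i in seq_len(n_ep)) {
    data[i, , ] <- synth_epoch(stages[i], config, child_seeds[i])
  }
  data <- data[perm, , , drop = FALSE]
  epoch_set(data, stages[perm], fs)
}

#' Build a toy hypnogram from run lengths
#'
#' Concatenates stage runs at 30 s epoch resolution, for exercising the
#' hypnogram-curation rules on known inputs.
#'
#' @param run_lengths Data frame (or tibble) with columns `stage` and `n`
#'   (epochs per run, `>= 1`), or a list of `c(stage, n)` pairs.
#' @return Character vector of stage labels, one per epoch.
#' @examples
#' synth_hypnogram(data.frame(stage = c("N2", "W", "N2"), n = c(5, 1, 5)))
#' @export
synth_hypnogram <- function(run_lengths) {
  if (is.list(run_lengths) && !is.data.frame(run_lengths)) {
    run_lengths <- tibble::tibble(
      stage = vapply(run_lengths, function(p) as.character(p[[1]]), ""),
      n = vapply(run_lengths, function(p) as.integer(p[[2]]), 1L)
    )
  }
  stopifnot(is.data.frame(run_lengths),
            all(c("stage", "n") %in% names(run_lengths)))
  if (nrow(run_lengths) == 0) stop("empty run-length table", call. = FALSE)
  n <- as.integer(run_lengths$n)
  if (any(is.na(n)) || any(n < 1)) {
    stop("run lengths must be >= 1", call. = FALSE)
  }
  rep(as.character(run_lengths$stage), times = n)
}
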