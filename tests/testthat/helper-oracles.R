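# Independent oracles used across test files. Deliberately naive
# implementations (loops, brute-force scans, explicit formulas) so they
# share no code path with the package internals they check.

naive_plv_matrix <- function(phase_epoch) {
  C <- nrow(phase_epoch)
  M <- diag(1, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      if (i != j) {
        d <- phase_epoch[i, ] - phase_epoch[j, ]
        M[i, j] <- sqrt(mean(cos(d))^2 + mean(sin(d))^2)
      }
    }
  }
  M
}

# scan all candidate thresholds drawn from the edge-weight set; return the
# largest at which every node keeps degree >= 1 under w >= tau
brute_force_tau <- function(m) {
  w <- m
  diag(w) <- NA
  cand <- sort(unique(as.numeric(w[!is.na(w)])))
  best <- NA
  for (tau in cand) {
    adj <- (m >= tau) * 1
    diag(adj) <- 0
    if (all(rowSums(adj) >= 1)) best <- tau
  }
  best
}

# textbook one-way ANOVA from explicit sums of squares
anova_ss <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# squared Pearson correlation between a feature and its 0/1 class indicator
pearson_indicator_r2 <- function(x_pos, x_neg) {
  x <- c(x_pos, x_neg)
  g <- c(rep(1, length(x_pos)), rep(0, length(x_neg)))
  stats::cor(x, g)^2
}

# fabricated tidy PLV table (no signal generation): one row per
# (epoch, band, pair), values N(mu, sd) with per-(stage, band) means
fake_feature_table <- function(epochs_per_stage, n_channels = 12,
                               mu = NULL, sd = 0.05, seed = 1,
                               bands = band_order()) {
  set.seed(seed)
  idx <- upper_pairs(n_channels)
  stages <- rep(stage_levels(), each = epochs_per_stage)
  purrr::map_dfr(seq_along(stages), function(e) {
    purrr::map_dfr(bands, function(b) {
      m <- if (is.null(mu)) 0.5 else mu[[stages[e]]][[b]]
      tibble::tibble(epoch = e, stage = stages[e], band = b,
                     pair_index = idx$pair_index, pair = idx$pair,
                     plv = pmin(pmax(stats::rnorm(nrow(idx), m, sd), 0), 1))
    })
  })
}

# small banded epoch set straight from the generator, for pipeline-level
# tests (fs = 128 keeps all six bands under Nyquist while staying fast)
tiny_dataset <- function(epochs_per_stage = 6, n_channels = 4, seed = 7,
                         coupling = default_coupling()) {
  synth_dataset(generator_config(
    n_channels = n_channels, sampling_rate = 128,
    epochs_per_stage = epochs_per_stage, seed = seed, coupling = coupling
  ))
}

# measured pairwise PLV of every epoch of one band, through the standard
# measurement chain (band-pass -> analytic phase -> trimmed PLV)
measure_band_plv <- function(es, band_name, edge_trim_s = 0.5) {
  bands <- eeg_bands()
  row <- bands[bands$band == band_name, ]
  banded <- filter_bank(es, row)
  feats <- plv_features(banded, edge_trim_s)
  feats
}
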