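test_that("instantaneous phase matches analytic closed forms", {
  fs <- 512
  t <- (0:(fs - 1)) / fs
  interior <- 100:400

  cosx <- matrix(cos(2 * pi * 10 * t), 1)
  ph <- instantaneous_phase(rbind(cosx, cosx))
  dphi <- diff(ph[1, interior])
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap steps
  expect_equal(dphi, rep(2 * pi * 10 / fs, length(dphi)), tolerance = 1e-6)

  # amplitude invariance
  x <- matrix(rnorm(2 * fs), 2)
  x[1, ] <- x[2, ] * 3
  ph2 <- instantaneous_phase(x)
  expect_equal(ph2[1, ], ph2[2, ], tolerance = 1e-10)

  # quadrature: sin lags cos by pi/2
  sc <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  ph3 <- instantaneous_phase(sc)
  d <- ph3[1, interior] - ph3[2, interior]
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(d, rep(-pi / 2, length(d)), tolerance = 1e-6)

  expect_error(instantaneous_phase(matrix(0, 2, 100)), "all-zero")
})

test_that("PLV obeys its analytic identities", {
  set.seed(4)
  a <- runif(500, -pi, pi)
  expect_equal(plv_pair(a, a), 1, tolerance = 1e-12)
  expect_equal(plv_pair(a, a - pi / 4), 1, tolerance = 1e-12)
  expect_lt(plv_pair(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4)), 1e-12)
  expect_error(plv_pair(a, a[-1]), "lengths differ")
})

test_that("mean PLV of iid uniform phases matches the resultant-length law", {
  set.seed(12)
  T_len <- 2000
  reps <- 300
  plvs <- replicate(reps, plv_pair(runif(T_len, -pi, pi),
                                   runif(T_len, -pi, pi)))
  target <- sqrt(pi / (4 * T_len))
  se <- sd(plvs) / sqrt(reps)
  expect_lt(abs(mean(plvs) - target), 3 * se)
})

test_that("matrix PLV equals the naive double loop and is well formed", {
  set.seed(9)
  for (rep in 1:5) {
    ph <- matrix(runif(12 * 600, -pi, pi), 12)
    M <- plv_matrix(ph)
    expect_equal(M, naive_plv_matrix(ph), tolerance = 1e-10)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
  # 2-channel special case and edge trimming
  ph2 <- matrix(runif(2 * 256, -pi, pi), 2)
  expect_equal(plv_matrix(ph2)[1, 2], plv_pair(ph2[1, ], ph2[2, ]),
               tolerance = 1e-12)
  Mt <- plv_matrix(ph2, edge_trim_s = 0.5, sampling_rate = 128)
  expect_equal(Mt[1, 2], plv_pair(ph2[1, 65:192], ph2[2, 65:192]),
               tolerance = 1e-12)
  expect_error(plv_matrix(ph2, edge_trim_s = 1, sampling_rate = 128),
               "no samples")
})

test_that("upper-triangle vectorization round-trips", {
  expect_identical(length(vectorize_upper(diag(12))), 66L)
  m3 <- matrix(0, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 0.1
  m3[1, 3] <- m3[3, 1] <- 0.2
  m3[2, 3] <- m3[3, 2] <- 0.3
  expect_equal(vectorize_upper(m3), c(0.1, 0.2, 0.3))
  diag(m3) <- 1
  expect_equal(matrix_from_upper(vectorize_upper(m3)), m3)
  expect_error(vectorize_upper(matrix(0, 2, 3)), "square")
})

test_that("stage averaging equals the explicit summation oracle", {
  set.seed(30)
  idx <- upper_pairs(4)
  feats <- purrr::map_dfr(1:50, function(e) {
    tibble::tibble(epoch = e, stage = sample(c("N2", "N3"), 1),
                   band = "alpha", pair_index = idx$pair_index,
                   pair = idx$pair, plv = runif(nrow(idx)))
  })
  m <- stage_mean_plv(feats, "N2")
  sub <- feats[feats$stage == "N2", ]
  for (k in seq_len(nrow(idx))) {
    v <- sub$plv[sub$pair_index == idx$pair_index[k]]
    expect_equal(m[idx$i[k], idx$j[k]], sum(v) / length(v),
                 tolerance = 1e-12)
  }
  one <- feats[feats$epoch == 1, ]
  m1 <- stage_mean_plv(one, one$stage[1])
  expect_equal(vectorize_upper(m1), one$plv, tolerance = 1e-12)
  expect_error(stage_mean_plv(feats, "REM"), "no epochs")
})

test_that("no-isolated-node threshold matches brute force", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.2
  res <- no_isolate_threshold(m)
  expect_equal(res$tau, 0.5)
  expect_equal(res$adjacency[1, 2], 1)
  expect_equal(res$adjacency[1, 3], 1)
  expect_equal(res$adjacency[2, 3], 0)
  expect_equal(rowSums(res$adjacency), c(2, 1, 1))

  w <- matrix(0.4, 5, 5); diag(w) <- 1
  resw <- no_isolate_threshold(w)
  expect_equal(resw$tau, 0.4)
  expect_true(all(resw$adjacency[upper.tri(w)] == 1))

  set.seed(77)
  for (rep in 1:20) {
    r <- matrix(runif(144), 12)
    r <- (r + t(r)) / 2; diag(r) <- 1
    res <- no_isolate_threshold(r)
    expect_identical(res$tau, brute_force_tau(r))
    expect_true(all(rowSums(res$adjacency) >= 1))
  }
  expect_error(no_isolate_threshold(matrix(1, 1, 1)), "2 nodes")
})

test_that("stage-difference networks are antisymmetric in their arguments", {
  set.seed(8)
  a <- matrix(runif(16), 4); a <- (a + t(a)) / 2
  b <- matrix(runif(16), 4); b <- (b + t(b)) / 2
  expect_true(all(network_difference(a, a) == 0))
  expect_equal(network_difference(a, b), -network_difference(b, a))
  expect_equal(network_difference(a, b)[1, 2], a[1, 2] - b[1, 2])
  expect_error(network_difference(a, matrix(0, 3, 3)), "shapes")
})

test_that("one-way ANOVA agrees with explicit sums of squares", {
  res0 <- stage_band_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)

  v <- c(0, 0.1, 0.2, 1, 1.1, 1.2)
  g <- rep(c("a", "b"), each = 3)
  got <- stage_band_anova(v, g)
  ora <- anova_ss(v, g)
  expect_equal(got$f, ora$f, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)

  set.seed(5)
  v3 <- rnorm(30)
  g3 <- rep(c("x", "y", "z"), 10)
  got3 <- stage_band_anova(v3, g3)
  ora3 <- anova_ss(v3, g3)
  expect_equal(got3$f, ora3$f, tolerance = 1e-10)
  expect_equal(got3$p, ora3$p, tolerance = 1e-10)

  expect_error(stage_band_anova(1:5, rep("a", 5)), "2 groups")
  expect_error(stage_band_anova(1:3, c("a", "a", "b")), ">= 2 values")
})

test_that("PLV bounds and symmetry hold across generated epochs", {
  es <- tiny_dataset(epochs_per_stage = 4)
  feats <- plv_features(filter_bank(es))
  expect_true(all(feats$plv >= 0 & feats$plv <= 1))
  expect_identical(nrow(feats), 12L * 6L * 6L)
  # one full-matrix check per band
  for (b in c("delta", "gamma")) {
    bd <- filter_bank(es, eeg_bands()[eeg_bands()$band == b, ])[[b]]
    ph <- instantaneous_phase(bd$data[1, , ])
    M <- plv_matrix(ph, 0.5, 128)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
})
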