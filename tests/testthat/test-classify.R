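test_that("stratified splits hit 75/25 within one sample per class", {
  labels <- rep(stage_levels(), each = 100)
  sp <- split_train_test(labels, seed = 3)
  expect_identical(length(sp$train), 225L)
  expect_identical(length(sp$test), 75L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  sp2 <- split_train_test(labels, seed = 3)
  expect_identical(sp, sp2)

  set.seed(19)
  for (rep in 1:100) {
    n_c <- sample(4:40, 3, replace = TRUE)
    lab <- rep(c("REM", "N2", "N3"), times = n_c)
    spl <- split_train_test(lab, seed = rep)
    for (cl in unique(lab)) {
      got <- sum(lab[spl$train] == cl)
      expect_lte(abs(got - 0.75 * sum(lab == cl)), 1)
    }
  }
  expect_error(split_train_test(c("a", "b", "b")), ">= 2 samples")
})

# well-separated three-cluster toy features
toy_clusters <- function(n_per = 20, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, sep, 0, 0, 0, sep), nrow = 3, ncol = d)
  y <- rep(stage_levels(), each = n_per)
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per * d), n_per) + matrix(centers[k, ], n_per, d,
                                             byrow = TRUE)
  }))
  list(x = x, y = y)
}

test_that("the SVM separates separable clusters and is deterministic", {
  tc <- toy_clusters()
  sp <- split_train_test(tc$y, seed = 5)
  m1 <- train_classifier(tc$x[sp$train, ], tc$y[sp$train])
  p1 <- predict(m1, tc$x[sp$test, ])
  expect_identical(p1, tc$y[sp$test])

  m2 <- train_classifier(tc$x[sp$train, ], tc$y[sp$train])
  expect_identical(p1, predict(m2, tc$x[sp$test, ]))

  sc <- predict(m1, tc$x[sp$test, ], type = "score")
  expect_identical(colnames(sc), sort(stage_levels()))
  expect_identical(stage_levels()[apply(
    sc[, stage_levels()], 1, which.max)], p1)

  expect_error(train_classifier(tc$x[1:5, ], rep("N2", 5)), "single class")
})

test_that("permuted labels put the SVM at chance", {
  accs <- vapply(1:20, function(s) {
    tc <- toy_clusters(n_per = 20, seed = s)
    set.seed(s + 1000)
    y <- sample(tc$y)
    sp <- split_train_test(y, seed = s)
    m <- train_classifier(tc$x[sp$train, ], y[sp$train])
    mean(predict(m, tc$x[sp$test, ]) == y[sp$test])
  }, 0)
  n_total <- 20 * 15
  se <- sqrt((1 / 3) * (2 / 3) / n_total)
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se)
})

test_that("classification reports satisfy their arithmetic invariants", {
  truth <- c(rep("REM", 10), rep("N2", 10), rep("N3", 10))
  pred <- truth
  pred[1:2] <- "N2"   # confusion [[8,2,0],[0,10,0],[0,0,10]] in REM/N2/N3 order
  rep_ <- evaluate(pred, truth)
  expect_equal(rep_$accuracy, 100 * 28 / 30, tolerance = 1e-12)
  expect_equal(unname(rep_$per_class_tpr[c("REM", "N2", "N3")]),
               c(80, 100, 100))
  expect_equal(rowSums(rep_$confusion)[c("REM", "N2", "N3")],
               c(REM = 10, N2 = 10, N3 = 10))
  expect_equal(sum(diag(rep_$confusion)) / sum(rep_$confusion) * 100,
               rep_$accuracy)

  perfect <- evaluate(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class_tpr == 100))

  expect_error(evaluate(character(0), character(0)), "empty")
  expect_error(evaluate(pred[-1], truth), "mismatch")

  g <- glance(rep_)
  expect_equal(g$accuracy, rep_$accuracy)
  td <- tidy(rep_)
  expect_equal(sum(td$n), 30L)
})

test_that("feature-level fusion concatenates bands with provenance", {
  feats <- fake_feature_table(epochs_per_stage = 3, n_channels = 12,
                              seed = 8)
  two <- feature_level_fusion(feats, c("delta", "alpha"))
  expect_identical(ncol(two), 2L + 132L)
  six <- feature_level_fusion(feats)
  expect_identical(ncol(six), 2L + 396L)
  expect_identical(sum(startsWith(names(six), "alpha_")), 66L)
  # canonical band order in columns
  first_band <- sub("_p.*", "", names(six)[-(1:2)])
  expect_identical(unique(first_band), band_order())

  one <- feature_level_fusion(feats, "alpha")
  expect_identical(ncol(one), 2L + 66L)
  expect_equal(one$alpha_p01,
               feats$plv[feats$band == "alpha" & feats$pair_index == 1])

  # sample-order mismatch across bands is rejected
  bad <- feats[!(feats$band == "alpha" & feats$epoch == 1), ]
  expect_error(feature_level_fusion(bad, c("delta", "alpha")), "ordering")
})

test_that("stacking and hybrid fusion validate their inputs", {
  feats <- fake_feature_table(epochs_per_stage = 8, n_channels = 4, seed = 2)
  sp <- split_train_test(rep(stage_levels(), each = 8), seed = 1)
  expect_error(decision_level_stacking(feats, "alpha", sp), ">= 2 bands")
  expect_error(hybrid_fusion(feats, band_pairs = list(c("delta", "beta1")),
                             split = sp), ">= 2 band groups")
})

test_that("the experiment grid is complete, consistent and reproducible", {
  mu <- list(
    REM = list(delta = 0.3, theta = 0.45, alpha = 0.65, beta1 = 0.45,
               beta2 = 0.65, gamma = 0.45),
    N2 = list(delta = 0.65, theta = 0.45, alpha = 0.3, beta1 = 0.45,
              beta2 = 0.65, gamma = 0.45),
    N3 = list(delta = 0.65, theta = 0.45, alpha = 0.65, beta1 = 0.45,
              beta2 = 0.3, gamma = 0.45)
  )
  feats <- fake_feature_table(epochs_per_stage = 16, n_channels = 4,
                              mu = mu, sd = 0.08, seed = 14)
  grid <- run_experiment_grid(feats, seed = 2)
  expect_identical(nrow(grid), 6L + 6L + 3L + 1L)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 100))
  expect_true(all(c("E", "E(C)") %in% grid$strategy))
  expect_true(any(grid$bands == paste(band_order(), collapse = "+")))

  grid2 <- run_experiment_grid(feats, seed = 2)
  expect_identical(grid, grid2)

  # complementary one-vs-rest bands: six-band fusion beats each single band
  six_c <- grid$accuracy[grid$strategy == "C" &
                           grid$bands == paste(band_order(), collapse = "+")]
  singles <- grid$accuracy[grid$strategy == "single"]
  expect_gte(six_c, max(singles))

  expect_error(run_experiment_grid(feats, strategies = "Z"),
               "unknown strategy")
})
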