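#' Stratified train/test split
#'
#' Seeded split with per-class proportions preserved to within one sample.
#'
#' @param labels Class label per sample.
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction = 0.75, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs >= 2 samples to split", call. = FALSE)
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1), length(idx) - 1)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train a Gaussian-kernel SVM on PLV features
#'
#' Radial-basis-kernel support vector classifier (libsvm via e1071) with
#' one-against-one multiclass decomposition. Features are standardized with
#' training-set mean and sd before fitting; the same transform is applied at
#' prediction time. Per-class decision scores (signed pairwise decision
#' values summed per class) are exposed for stacking.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels.
#' @param cost Soft-margin cost C (default 1).
#' @param gamma Kernel width; default `1 / n_features` on standardized
#'   features.
#' @return Object of class `plv_svm`.
#' @export
train_classifier <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) < 2) stop("training data has a single class", call. = FALSE)
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sdev, levels = levels(y),
                 cost = cost, gamma = gamma),
            class = "plv_svm")
}

#' @export
predict.plv_svm <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  xs <- scale(as.matrix(newdata), center = object$mu, scale = object$sd)
  if (type == "class") {
    return(as.character(predict(object$fit, xs)))
  }
  dv <- attr(predict(object$fit, xs, decision.values = TRUE),
             "decision.values")
  scores <- matrix(0, nrow = nrow(xs), ncol = length(object$levels),
                   dimnames = list(NULL, object$levels))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  scores
}

#' Classification report
#'
#' Accuracy (percent), per-class true-positive rates and the confusion
#' matrix (rows = true class, columns = predicted).
#'
#' @param predictions Predicted labels.
#' @param truth True labels (same length, non-empty).
#' @param strategy Strategy tag (`"single"`, `"C"`, `"E"`, `"E(C)"`).
#' @param bands Band subset the features came from.
#' @return Object of class `classification_report`.
#' @export
evaluate <- function(predictions, truth, strategy = "single",
                     bands = character()) {
  if (length(predictions) != length(truth)) {
    stop("prediction/truth length mismatch", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty test set", call. = FALSE)
  lv <- sort(unique(c(as.character(truth), as.character(predictions))))
  conf <- table(factor(truth, levels = lv), factor(predictions, levels = lv))
  conf <- unclass(as.matrix(conf))
  acc <- 100 * sum(diag(conf)) / sum(conf)
  tpr <- 100 * diag(conf) / pmax(rowSums(conf), 1)
  structure(
    list(accuracy = acc, per_class_tpr = tpr, confusion = conf,
         strategy = strategy, bands = bands, n_test = length(truth)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> strategy=%s bands=[%s]\n",
              x$strategy, paste(x$bands, collapse = ",")))
  cat(sprintf("  accuracy: %.2f%% (n_test=%d)\n", x$accuracy, x$n_test))
  cat("  per-class TPR (%):",
      paste(sprintf("%s=%.2f", names(x$per_class_tpr), x$per_class_tpr),
            collapse = ", "), "\n")
  invisible(x)
}

# wide sample-by-feature matrix for a band subset, rows ordered by epoch
feature_matrix <- function(features, bands) {
  stopifnot(all(bands %in% unique(features$band)))
  ref <- NULL
  cols <- list()
  for (b in bands) {
    sub <- features[features$band == b, ]
    sub <- sub[order(sub$epoch, sub$pair_index), ]
    lab <- sub[!duplicated(sub$epoch), c("epoch", "stage")]
    if (is.null(ref)) {
      ref <- lab
    } else if (!identical(lab$epoch, ref$epoch) ||
               !identical(lab$stage, ref$stage)) {
      stop("sample ordering differs between bands", call. = FALSE)
    }
    wide <- matrix(sub$plv, nrow = nrow(lab), byrow = TRUE)
    colnames(wide) <- sprintf("%s_p%02d", b,
                              sort(unique(sub$pair_index)))
    cols[[b]] <- wide
  }
  x <- do.call(cbind, cols)
  list(x = x, y = ref$stage, epochs = ref$epoch)
}

#' Feature-level band fusion
#'
#' Concatenates the per-band PLV feature columns (canonical band order) into
#' one wide sample-by-feature table: the "C" strategy's input. Column names
#' `band_pNN` carry the (band, channel pair) provenance.
#'
#' @param features Tidy PLV table from [plv_features()].
#' @param bands Band subset to fuse (default: all present, canonical order).
#' @return Tibble with columns `epoch`, `stage`, then one column per
#'   (band, pair) feature.
#' @export
feature_level_fusion <- function(features, bands = NULL) {
  present <- unique(as.character(features$band))
  if (is.null(bands)) bands <- intersect(band_order(), present)
  fm <- feature_matrix(features, bands)
  dplyr::bind_cols(
    tibble::tibble(epoch = fm$epochs, stage = fm$y),
    tibble::as_tibble(fm$x)
  )
}

#' Single-band or feature-fused SVM classification
#'
#' Trains on the training split of the (possibly fused) feature matrix and
#' reports on the test split.
#'
#' @param features Tidy PLV table.
#' @param bands Band subset (length 1 = single band; >1 = "C" fusion).
#' @param split A [split_train_test()] result.
#' @param cost,gamma SVM hyperparameters (see [train_classifier()]).
#' @return A [evaluate()] report.
#' @export
classify_bands <- function(features, bands, split, cost = 1, gamma = NULL) {
  fm <- feature_matrix(features, bands)
  model <- train_classifier(fm$x[split$train, , drop = FALSE],
                            fm$y[split$train], cost = cost, gamma = gamma)
  pred <- predict(model, fm$x[split$test, , drop = FALSE])
  evaluate(pred, fm$y[split$test],
           strategy = if (length(bands) > 1) "C" else "single",
           bands = bands)
}

# out-of-fold per-class scores on the training split + test-split scores,
# for a list of feature matrices (one per base classifier)
stacked_scores <- function(xs, y, split, cost, gamma, seed, n_folds = 5) {
  tr <- split$train
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(tr)))
  lv <- sort(unique(as.character(y[tr])))
  meta_tr <- NULL
  meta_te <- NULL
  for (x in xs) {
    sc_tr <- matrix(NA_real_, length(tr), length(lv))
    for (f in seq_len(n_folds)) {
      in_f <- fold == f
      if (length(unique(as.character(y[tr[!in_f]]))) < 2) {
        stop("fold left a single class; too few samples for stacking",
             call. = FALSE)
      }
      m <- train_classifier(x[tr[!in_f], , drop = FALSE], y[tr[!in_f]],
                            cost = cost, gamma = gamma)
      sc <- predict(m, x[tr[in_f], , drop = FALSE], type = "score")
      sc_tr[in_f, ] <- sc[, lv, drop = FALSE]
    }
    m_full <- train_classifier(x[tr, , drop = FALSE], y[tr],
                               cost = cost, gamma = gamma)
    sc_te <- predict(m_full, x[split$test, , drop = FALSE], type = "score")
    meta_tr <- cbind(meta_tr, sc_tr)
    meta_te <- cbind(meta_te, sc_te[, lv, drop = FALSE])
  }
  list(train = meta_tr, test = meta_te)
}

#' Decision-level fusion by stacking ("E")
#'
#' One base SVM per band on the training split; meta-features are each base
#' classifier's per-class decision scores, produced out-of-fold (internal
#' seeded 5-fold) on the training split so the meta classifier never sees
#' its own training predictions. The meta SVM is evaluated on the untouched
#' test split.
#'
#' @param features Tidy PLV table.
#' @param bands Bands providing base classifiers (`>= 2`).
#' @param split A [split_train_test()] result.
#' @param cost,gamma Base/meta SVM hyperparameters.
#' @param seed Seed for the internal fold assignment.
#' @param n_folds Internal folds (default 5).
#' @return A [evaluate()] report with strategy `"E"`.
#' @export
decision_level_stacking <- function(features, bands, split, cost = 1,
                                    gamma = NULL, seed = 1, n_folds = 5) {
  if (length(bands) < 2) {
    stop("stacking needs >= 2 bands", call. = FALSE)
  }
  fms <- lapply(bands, function(b) feature_matrix(features, b))
  y <- fms[[1]]$y
  xs <- lapply(fms, `[[`, "x")
  ms <- stacked_scores(xs, y, split, cost, gamma, seed, n_folds)
  meta <- train_classifier(ms$train, y[split$train], cost = cost)
  pred <- predict(meta, ms$test)
  evaluate(pred, y[split$test], strategy = "E", bands = bands)
}

#' Hybrid fusion ("E(C)")
#'
#' Feature-level fusion within each band pair, one base SVM per pair, then
#' the stacking ensemble over the pair classifiers.
#'
#' @param features Tidy PLV table.
#' @param band_pairs List of band subsets (default: the three complementary
#'   pairs delta+beta1, theta+gamma, alpha+beta2).
#' @param split A [split_train_test()] result.
#' @param cost,gamma SVM hyperparameters.
#' @param seed Seed for the internal fold assignment.
#' @return A [evaluate()] report with strategy `"E(C)"`.
#' @export
hybrid_fusion <- function(features,
                          band_pairs = list(c("delta", "beta1"),
                                            c("theta", "gamma"),
                                            c("alpha", "beta2")),
                          split, cost = 1, gamma = NULL, seed = 1) {
  if (length(band_pairs) < 2) {
    stop("hybrid fusion needs >= 2 band groups", call. = FALSE)
  }
  fms <- lapply(band_pairs, function(bp) feature_matrix(features, bp))
  y <- fms[[1]]$y
  xs <- lapply(fms, `[[`, "x")
  ms <- stacked_scores(xs, y, split, cost, gamma, seed)
  meta <- train_classifier(ms$train, y[split$train], cost = cost)
  pred <- predict(meta, ms$test)
  evaluate(pred, y[split$test], strategy = "E(C)",
           bands = unique(unlist(band_pairs)))
}

#' Run the full band-fusion experiment grid
#'
#' Reproduces the standard experiment layout: each single band, the three
#' two-band feature fusions, the three-band set (alpha, beta1, delta) with
#' "C" and "E", the four-band set adding gamma, and all six bands with "C",
#' "E" and "E(C)".
#'
#' @param features Tidy PLV table (all six bands).
#' @param seed Split/stacking seed.
#' @param train_fraction Training fraction (default 0.75).
#' @param cost,gamma SVM hyperparameters.
#' @param strategies Subset of `c("single", "C", "E", "E(C)")` to run.
#' @return Tibble with one row per (strategy, band set): columns `strategy`,
#'   `bands`, `accuracy`, and per-class TPR columns.
#' @export
run_experiment_grid <- function(features, seed = 1, train_fraction = 0.75,
                                cost = 1, gamma = NULL,
                                strategies = c("single", "C", "E", "E(C)")) {
  bad <- setdiff(strategies, c("single", "C", "E", "E(C)"))
  if (length(bad)) {
    stop("unknown strategy label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fm0 <- feature_matrix(features, intersect(band_order(),
                                            unique(features$band)))
  split <- split_train_test(fm0$y, train_fraction, seed)
  rows <- list()
  add <- function(rep) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      strategy = rep$strategy,
      bands = paste(rep$bands, collapse = "+"),
      accuracy = rep$accuracy,
      tpr_REM = unname(rep$per_class_tpr["REM"]),
      tpr_N2 = unname(rep$per_class_tpr["N2"]),
      tpr_N3 = unname(rep$per_class_tpr["N3"])
    )
  }
  if ("single" %in% strategies) {
    for (b in band_order()) {
      add(classify_bands(features, b, split, cost, gamma))
    }
  }
  if ("C" %in% strategies) {
    for (bp in list(c("delta", "beta1"), c("theta", "gamma"),
                    c("alpha", "beta2"), c("alpha", "beta1", "delta"),
                    c("alpha", "beta1", "delta", "gamma"), band_order())) {
      add(classify_bands(features, bp, split, cost, gamma))
    }
  }
  if ("E" %in% strategies) {
    for (bp in list(c("alpha", "beta1", "delta"),
                    c("alpha", "beta1", "delta", "gamma"), band_order())) {
      add(decision_level_stacking(features, bp, split, cost, gamma, seed))
    }
  }
  if ("E(C)" %in% strategies) {
    add(hybrid_fusion(features, split = split, cost = cost, gamma = gamma,
                      seed = seed))
  }
  dplyr::bind_rows(rows)
}
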