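#' Instantaneous phase of a narrowband epoch
#'
#' Angle of the analytic signal, per channel. Amplitude-invariant: scaling a
#' channel by any positive constant leaves its phase unchanged.
#'
#' @param epoch `channels x samples` numeric matrix (one filter-bank output).
#' @return `channels x samples` matrix of phases in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(epoch) {
  stopifnot(is.matrix(epoch))
  if (any(apply(epoch, 1, function(ch) all(ch == 0)))) {
    stop("phase undefined for an all-zero channel", call. = FALSE)
  }
  t(apply(epoch, 1, function(ch) Arg(analytic_signal(ch))))
}

#' Phase-locking value of two phase series
#'
#' Modulus of the time-averaged complex unit vector of the phase difference:
#' `PLV = |mean(exp(i * (phi_a - phi_b)))|`, averaged over the samples of one
#' epoch. 1 means a perfectly consistent phase relation (any fixed lag),
#' 0 means no consistent relation.
#'
#' @param phase_a,phase_b Equal-length numeric phase series (radians).
#' @return Scalar in `[0, 1]`.
#' @export
plv_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series lengths differ", call. = FALSE)
  }
  if (length(phase_a) < 1) stop("empty phase series", call. = FALSE)
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Pairwise PLV matrix of one epoch
#'
#' All-pairs [plv_pair()] across channels, computed in one complex matrix
#' product. Symmetric with unit diagonal.
#'
#' @param phase_epoch `channels x samples` phase matrix (radians).
#' @param edge_trim_s Seconds to discard at each epoch edge before averaging
#'   (suppresses analytic-transform edge artifacts); requires
#'   `sampling_rate`.
#' @param sampling_rate Hz, needed only when `edge_trim_s > 0`.
#' @return `C x C` numeric matrix in `[0, 1]`.
#' @export
plv_matrix <- function(phase_epoch, edge_trim_s = 0, sampling_rate = NULL) {
  stopifnot(is.matrix(phase_epoch), nrow(phase_epoch) >= 2)
  if (edge_trim_s > 0) {
    if (is.null(sampling_rate)) {
      stop("sampling_rate required when edge_trim_s > 0", call. = FALSE)
    }
    trim <- round(edge_trim_s * sampling_rate)
    n <- ncol(phase_epoch)
    if (2 * trim >= n) stop("edge trim leaves no samples", call. = FALSE)
    phase_epoch <- phase_epoch[, (trim + 1):(n - trim), drop = FALSE]
  }
  Z <- exp(1i * phase_epoch)
  M <- Mod(Z %*% Conj(t(Z))) / ncol(phase_epoch)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  pmin(M, 1)
}

#' Upper-triangle feature order
#'
#' The fixed row-major (i, j) index map used to vectorize `C x C` symmetric
#' PLV matrices into `C(C-1)/2` features.
#'
#' @param n_channels Number of channels.
#' @param channel_labels Optional channel names for the `pair` label.
#' @return Tibble with columns `pair_index`, `i`, `j`, `pair`.
#' @export
upper_pairs <- function(n_channels, channel_labels = NULL) {
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(n_channels))
  }
  ij <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  tibble::tibble(
    pair_index = seq_len(nrow(ij)),
    i = as.integer(ij[, "row"]), j = as.integer(ij[, "col"]),
    pair = paste(channel_labels[ij[, "row"]], channel_labels[ij[, "col"]],
                 sep = "|")
  )
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-major order excluding the diagonal; the inverse
#' [matrix_from_upper()] reconstructs the symmetric matrix with unit
#' diagonal.
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length `C(C-1)/2`.
#' @export
vectorize_upper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("need a square matrix", call. = FALSE)
  }
  idx <- upper_pairs(nrow(m))
  m[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' @param v Vector of length `C(C-1)/2`.
#' @param diag_value Diagonal fill (1 for PLV matrices).
#' @return `C x C` symmetric matrix.
#' @export
matrix_from_upper <- function(v, diag_value = 1) {
  C <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(C - round(C)) > 1e-9) {
    stop("vector length is not C(C-1)/2 for integer C", call. = FALSE)
  }
  C <- round(C)
  idx <- upper_pairs(C)
  m <- matrix(0, C, C)
  m[cbind(idx$i, idx$j)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Tidy PLV feature table for a banded epoch set
#'
#' Runs phase extraction and the pairwise PLV over every epoch of every
#' band, returning the long tidy table the ranking and classification stages
#' consume: one row per (epoch, band, channel pair).
#'
#' @param banded Named list of narrowband [epoch_set()]s (a [filter_bank()]
#'   output), or a single [epoch_set()].
#' @param edge_trim_s Seconds trimmed from each epoch edge (default 0.5).
#' @return Tibble with columns `epoch`, `stage`, `band`, `pair_index`,
#'   `pair`, `plv`.
#' @export
plv_features <- function(banded, edge_trim_s = 0.5) {
  if (inherits(banded, "epoch_set")) {
    nm <- if (is.null(banded$band)) "broadband" else banded$band
    banded <- stats::setNames(list(banded), nm)
  }
  purrr::imap_dfr(banded, function(es, band_name) {
    if (length(es) == 0) {
      return(tibble::tibble(epoch = integer(), stage = character(),
                            band = character(), pair_index = integer(),
                            pair = character(), plv = numeric()))
    }
    idx <- upper_pairs(n_channels(es), es$channel_labels)
    purrr::map_dfr(seq_len(length(es)), function(i) {
      ph <- instantaneous_phase(es$data[i, , ])
      M <- plv_matrix(ph, edge_trim_s, es$sampling_rate)
      tibble::tibble(epoch = i, stage = es$labels[i], band = band_name,
                     pair_index = idx$pair_index, pair = idx$pair,
                     plv = M[cbind(idx$i, idx$j)])
    })
  })
}

#' Stage-average PLV matrix
#'
#' Entrywise mean of the per-epoch PLV matrices belonging to one stage.
#'
#' @param features Tidy PLV table from [plv_features()], single band.
#' @param stage Stage label.
#' @return `C x C` symmetric matrix (unit diagonal).
#' @export
stage_mean_plv <- function(features, stage) {
  stopifnot(is.data.frame(features))
  if (length(unique(features$band)) > 1) {
    stop("stage_mean_plv expects a single band; filter first", call. = FALSE)
  }
  sub <- features[features$stage == stage, , drop = FALSE]
  if (nrow(sub) == 0) stop("no epochs with stage ", stage, call. = FALSE)
  means <- tapply(sub$plv, sub$pair_index, mean)
  matrix_from_upper(as.numeric(means[order(as.integer(names(means)))]))
}

#' No-isolated-node network threshold
#'
#' The largest PLV threshold at which the binarized stage-average network
#' has no isolated node. Closed form: the minimum over nodes of each node's
#' strongest edge (`tau = min_i max_{j != i} w_ij`); edges with weight
#' `>= tau` are kept, so every node retains at least its strongest edge and
#' any strictly larger edge-weight threshold isolates the weakest node.
#'
#' @param m Square symmetric weight matrix (`>= 2` nodes).
#' @return List with elements `tau` (scalar) and `adjacency` (0/1 matrix,
#'   zero diagonal).
#' @export
no_isolate_threshold <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    stop("need a square matrix with >= 2 nodes", call. = FALSE)
  }
  w <- m
  diag(w) <- -Inf
  tau <- min(apply(w, 1, max))
  adj <- (m >= tau) * 1
  diag(adj) <- 0
  list(tau = tau, adjacency = adj)
}

#' Signed stage-difference network
#'
#' Entrywise `mat_a - mat_b`; positive entries are connections stronger in
#' the first stage.
#'
#' @param mat_a,mat_b Same-shape matrices.
#' @return Signed matrix.
#' @export
network_difference <- function(mat_a, mat_b) {
  if (!all(dim(mat_a) == dim(mat_b))) {
    stop("matrix shapes differ", call. = FALSE)
  }
  mat_a - mat_b
}

#' One-way ANOVA on per-epoch mean PLV
#'
#' Each epoch is summarized by its mean PLV over channel pairs; groups are
#' compared with a standard one-way ANOVA. Lower p means a more significant
#' group difference.
#'
#' @param values Numeric vector of per-epoch mean PLV.
#' @param groups Grouping labels (stage or band), same length.
#' @return List with `f` and `p`.
#' @export
stage_band_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) { f <- 0; p <- 1 }   # zero between-group variance
  list(f = f, p = p)
}

#' Per-epoch mean PLV summary
#'
#' Collapses a tidy PLV table to one row per (epoch, band): the mean PLV
#' over channel pairs -- the operand of the stage/band comparisons.
#'
#' @param features Tidy table from [plv_features()].
#' @return Tibble with columns `epoch`, `stage`, `band`, `mean_plv`.
#' @export
epoch_mean_plv <- function(features) {
  dplyr::summarise(
    dplyr::group_by(features, .data$epoch, .data$stage, .data$band),
    mean_plv = mean(.data$plv), .groups = "drop"
  )
}
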