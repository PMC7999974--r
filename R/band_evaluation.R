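#' Point-biserial r-squared of one feature for a two-class contrast
#'
#' `r = sqrt(N+ N-) / (N+ + N-) * (mean(X+) - mean(X-)) / sd(X+ u X-)` with
#' the population standard deviation of the pooled sample; the squared value
#' is returned. Equal to the squared Pearson correlation between the feature
#' and a 0/1 class indicator, so it lies in `[0, 1]` and equals exactly 1
#' under perfect separation of two constant groups.
#'
#' @param x_pos,x_neg Feature values of the two classes (each non-empty).
#' @return Scalar in `[0, 1]`.
#' @export
biserial_r2 <- function(x_pos, x_neg) {
  n_pos <- length(x_pos); n_neg <- length(x_neg)
  if (n_pos < 1 || n_neg < 1) stop("both classes need samples", call. = FALSE)
  pooled <- c(x_pos, x_neg)
  n <- n_pos + n_neg
  s <- sqrt(mean((pooled - mean(pooled))^2))   # population sd
  if (s == 0) stop("pooled values are constant", call. = FALSE)
  r <- sqrt(n_pos * n_neg) / n * (mean(x_pos) - mean(x_neg)) / s
  r^2
}

class_pairs <- function() {
  list(c("REM", "N2"), c("REM", "N3"), c("N2", "N3"))
}

#' Score every (class pair, band, channel pair) feature
#'
#' Computes the point-biserial r-squared of each PLV feature for each of the
#' three stage contrasts and returns the globally ranked table
#' (3 class pairs x bands x channel pairs rows). Sorting is by r-squared
#' descending with deterministic tie-breaks (band order, then pair index).
#'
#' @param features Tidy PLV table from [plv_features()].
#' @return A ranking tibble of class `plv_ranking` with columns
#'   `class_pair`, `band`, `pair_index`, `pair`, `r2`, `rank`.
#' @export
score_all <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("stage", "band", "pair_index", "plv") %in% names(features)))
  present <- unique(features$stage)
  need <- stage_levels()
  if (!all(need %in% present)) {
    stop("missing class: ", paste(setdiff(need, present), collapse = ", "),
         call. = FALSE)
  }
  recs <- purrr::map_dfr(class_pairs(), function(cp) {
    sub <- features[features$stage %in% cp, , drop = FALSE]
    dplyr::summarise(
      dplyr::group_by(sub, .data$band, .data$pair_index, .data$pair),
      r2 = biserial_r2(.data$plv[.data$stage == cp[1]],
                       .data$plv[.data$stage == cp[2]]),
      .groups = "drop"
    ) |>
      dplyr::mutate(class_pair = paste(cp, collapse = "|"))
  })
  band_lv <- intersect(band_order(), unique(recs$band))
  recs$band <- factor(recs$band, levels = band_lv)
  recs <- dplyr::arrange(recs, dplyr::desc(.data$r2), .data$band,
                         .data$pair_index)
  recs$rank <- seq_len(nrow(recs))
  out <- recs[, c("class_pair", "band", "pair_index", "pair", "r2", "rank")]
  class(out) <- c("plv_ranking", class(out))
  out
}

#' Band shares among the top-k ranked features
#'
#' Percentage of the `k` highest-r-squared records (pooled across the three
#' class pairs) that belong to each band; percentages sum to 100.
#'
#' @param ranking A [score_all()] table.
#' @param k Number of top records (`1 <= k <= nrow(ranking)`).
#' @return Tibble with columns `band`, `percent` (one row per band present).
#' @export
top_k_band_percentage <- function(ranking, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds number of records", call. = FALSE)
  top <- ranking[order(ranking$rank), ][seq_len(k), ]
  counts <- table(factor(top$band, levels = levels(ranking$band)))
  tibble::tibble(
    band = factor(names(counts), levels = levels(ranking$band)),
    percent = 100 * as.numeric(counts) / k
  )
}

#' Discriminative ratio per band for each stage contrast
#'
#' For each class pair, take its `t` largest-r-squared records across all
#' bands, sum r-squared within each band, and normalize by the total: the
#' share of top-t discriminative mass carried by each band. Ratios sum to 1
#' within each class pair.
#'
#' @param ranking A [score_all()] table.
#' @param t Number of top records per class pair (default 36).
#' @return Tibble with columns `class_pair`, `band`, `ratio`.
#' @export
discriminative_ratio <- function(ranking, t = 36) {
  if (t <= 0) stop("t must be positive", call. = FALSE)
  purrr::map_dfr(unique(ranking$class_pair), function(cp) {
    sub <- ranking[ranking$class_pair == cp, ]
    if (nrow(sub) < t) {
      stop("fewer than t records for class pair ", cp, call. = FALSE)
    }
    top <- sub[order(-sub$r2, as.integer(sub$band), sub$pair_index), ][
      seq_len(t), ]
    mass <- tapply(top$r2, factor(top$band, levels = levels(ranking$band)),
                   sum, default = 0)
    tibble::tibble(class_pair = cp,
                   band = factor(names(mass), levels = levels(ranking$band)),
                   ratio = as.numeric(mass) / sum(top$r2))
  })
}

#' Two best features by class-pair-averaged r-squared
#'
#' For each (band, channel pair) feature, averages its three class-pair
#' r-squared values; within each band the two features with the largest
#' averages are selected (ties broken by pair index) and their per-epoch
#' values returned for 2-D visualization.
#'
#' @param ranking A [score_all()] table.
#' @param features Tidy PLV table the ranking was computed from.
#' @return Tibble with columns `band`, `epoch`, `stage`, `feature`
#'   (`"feature1"`/`"feature2"`), `pair_index`, `pair`, `plv`.
#' @export
select_2d_features <- function(ranking, features) {
  avg <- dplyr::summarise(
    dplyr::group_by(ranking, .data$band, .data$pair_index, .data$pair),
    r2_bar = mean(.data$r2), .groups = "drop"
  )
  purrr::map_dfr(levels(droplevels(avg$band)), function(b) {
    sub <- avg[avg$band == b, ]
    if (nrow(sub) < 2) stop("fewer than two features in band ", b,
                            call. = FALSE)
    sub <- sub[order(-sub$r2_bar, sub$pair_index), ]
    sel <- sub[1:2, ]
    vals <- features[features$band == b &
                       features$pair_index %in% sel$pair_index, ]
    vals$feature <- ifelse(vals$pair_index == sel$pair_index[1],
                           "feature1", "feature2")
    tibble::tibble(band = b, epoch = vals$epoch, stage = vals$stage,
                   feature = vals$feature, pair_index = vals$pair_index,
                   pair = vals$pair, plv = vals$plv)
  })
}
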