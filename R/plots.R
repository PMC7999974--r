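# ggplot2 views of the main result types. Each returns the plot object
# without printing; all values shown are taken from the tables as computed.

#' Stage-by-band mean PLV bars
#'
#' Bar chart of mean PLV per (band, stage) with standard-error bars --
#' the stage-contrast view of the connectivity analysis.
#'
#' @param features Tidy PLV table from [plv_features()].
#' @return A ggplot object.
#' @export
plot_stage_band_plv <- function(features) {
  summ <- dplyr::summarise(
    dplyr::group_by(epoch_mean_plv(features), .data$band, .data$stage),
    mean = mean(.data$mean_plv),
    se = stats::sd(.data$mean_plv) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  summ$band <- factor(summ$band, levels = band_order())
  summ$stage <- factor(summ$stage, levels = stage_levels())
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$band, y = .data$mean,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = "frequency band", y = "mean PLV", fill = "stage") +
    ggplot2::theme_minimal()
}

#' Top-k band percentage bars
#'
#' @param ranking A [score_all()] table.
#' @param ks Values of k to show (default 95 and 140).
#' @return A ggplot object.
#' @export
plot_band_percentages <- function(ranking, ks = c(95, 140)) {
  df <- purrr::map_dfr(ks, function(k) {
    dplyr::mutate(top_k_band_percentage(ranking, k), k = factor(k))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$percent,
                                   fill = .data$k)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::labs(x = "frequency band", y = "percent of top-k features",
                  fill = "k") +
    ggplot2::theme_minimal()
}

#' Discriminative-ratio bars per stage contrast
#'
#' @param ratios A [discriminative_ratio()] table.
#' @return A ggplot object.
#' @export
plot_discriminative_ratio <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$band, y = .data$ratio,
                                       fill = .data$class_pair)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::labs(x = "frequency band", y = "discriminative ratio",
                  fill = "stage pair") +
    ggplot2::theme_minimal()
}

#' 2-D feature scatter per band
#'
#' @param sel2d A [select_2d_features()] table.
#' @return A ggplot object (facetted by band).
#' @export
plot_2d_features <- function(sel2d) {
  wide <- tidyr::pivot_wider(
    sel2d[, c("band", "epoch", "stage", "feature", "plv")],
    names_from = "feature", values_from = "plv"
  )
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$feature1, y = .data$feature2,
                                     colour = .data$stage)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~band, scales = "free") +
    ggplot2::labs(x = "feature 1 (PLV)", y = "feature 2 (PLV)",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_stage_band_plv autoplot method for ranking tables.
#' @param object A `plv_ranking`.
#' @param ... Passed to [plot_band_percentages()].
#' @export
autoplot.plv_ranking <- function(object, ...) {
  plot_band_percentages(object, ...)
}

#' Confusion-matrix heat map
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      title = sprintf("%s [%s]: %.2f%%", object$strategy,
                      paste(object$bands, collapse = "+"), object$accuracy),
      x = "predicted", y = "true"
    ) +
    ggplot2::theme_minimal()
}
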