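#' Tidy a classification report
#'
#' One row per (true class, predicted class) confusion cell.
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `prediction`, `n`.
#' @export
tidy.classification_report <- function(x, ...) {
  conf <- x$confusion
  tibble::tibble(
    truth = rep(rownames(conf), times = ncol(conf)),
    prediction = rep(colnames(conf), each = nrow(conf)),
    n = as.integer(conf)
  )
}

#' One-row summary of a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One-row tibble: `strategy`, `bands`, `accuracy`, per-class TPR,
#'   `n_test`.
#' @export
glance.classification_report <- function(x, ...) {
  out <- tibble::tibble(
    strategy = x$strategy,
    bands = paste(x$bands, collapse = "+"),
    accuracy = x$accuracy,
    n_test = x$n_test
  )
  for (cl in names(x$per_class_tpr)) {
    out[[paste0("tpr_", cl)]] <- unname(x$per_class_tpr[cl])
  }
  out
}

#' Tidy a feature ranking
#'
#' The ranking is already tabular; this strips the class for pipeline use.
#'
#' @param x A `plv_ranking` from [score_all()].
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.plv_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row-per-band summary of a feature ranking
#'
#' Best rank, best and median r-squared per band.
#'
#' @param x A `plv_ranking`.
#' @param ... Unused.
#' @return Tibble with one row per band.
#' @export
glance.plv_ranking <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(unclass(x)[names(x)]), .data$band),
    best_rank = min(.data$rank),
    max_r2 = max(.data$r2),
    median_r2 = stats::median(.data$r2),
    .groups = "drop"
  )
}
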