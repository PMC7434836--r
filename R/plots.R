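#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an incremental selection curve
#'
#' Line chart of cross-validated metrics against subset dimension, the
#' standard way of eyeballing where adding ranked features stops paying off.
#' Slope points from [knee_points()] can be highlighted.
#'
#' @param object An `acp_curve` from [incremental_curve()].
#' @param metrics Which metric columns to draw (default `"f_score"`).
#' @param knee Optional result of [knee_points()] to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acp_curve <- function(object, metrics = "f_score", knee = NULL, ...) {
  stopifnot(all(metrics %in% names(object)))
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("dimension", metrics))),
    -"dimension", names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$dimension,
                                          y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "dimension (top-m ranked features)", y = "metric",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(knee) && nrow(knee)) {
    pts <- dplyr::semi_join(tibble::as_tibble(object),
                            tibble::as_tibble(knee), by = "dimension")
    p <- p + ggplot2::geom_point(
      data = tidyr::pivot_longer(
        dplyr::select(pts, dplyr::all_of(c("dimension", metrics))),
        -"dimension", names_to = "metric", values_to = "value"),
      colour = "red", size = 2)
  }
  p
}

#' Plot a hyperparameter grid search
#'
#' Accuracy heat map over the (c, g) grid of [grid_search_svm()].
#'
#' @param object An `acp_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acp_grid <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(log2(.data$c)),
                               y = factor(log2(.data$g)),
                               fill = .data$acc)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "log2(c)", y = "log2(g)", fill = "CV Acc") +
    ggplot2::theme_minimal()
}

#' Plot a feature ranking
#'
#' Bar chart of the top-ranked features' composite scores split into the
#' relevance and distance components.
#'
#' @param object An `acp_ranking`.
#' @param top_n How many leading features to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acp_ranking <- function(object, top_n = 20L, ...) {
  top <- utils::head(tibble::as_tibble(object), top_n)
  long <- tidyr::pivot_longer(
    dplyr::select(top, dplyr::all_of(c("feature", "relevance", "distance"))),
    -"feature", names_to = "component", values_to = "value")
  long$feature <- factor(long$feature, levels = rev(top$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$feature,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
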