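#' Plot condition mean traces with SEM ribbons
#'
#' @param summaries Output of [condition_mean_sem()].
#' @return A ggplot faceted by biosensor, coloured by condition.
#' @export
plot_trajectories <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$time_min, .data$mean,
                               colour = .data$condition_id,
                               fill = .data$condition_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$biosensor_id),
                        scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "normalized FRET ratio",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot K-means trajectory pattern centroids
#'
#' @param object A `kmeans_patterns` object.
#' @param ... Unused.
#' @return A ggplot of the k centroid traces.
#' @export
autoplot.kmeans_patterns <- function(object, ...) {
  df <- tibble::as_tibble(object$centroids) |>
    dplyr::mutate(cluster = factor(seq_len(nrow(object$centroids)))) |>
    tidyr::pivot_longer(-"cluster", names_to = "idx",
                        values_to = "value") |>
    dplyr::mutate(time_min = rep(object$time_grid,
                                 times = nrow(object$centroids)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "normalized response",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of dynamic signatures
#'
#' @param signatures Output of [cluster_proportions()].
#' @return A ggplot of cluster proportions per condition.
#' @export
plot_signatures <- function(signatures) {
  p <- ggplot2::ggplot(signatures,
                       ggplot2::aes(.data$condition_id, .data$proportion,
                                    fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "condition", y = "proportion of cells",
                  fill = "pattern") +
    ggplot2::theme_minimal()
  if ("biosensor_id" %in% names(signatures)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$biosensor_id))
  }
  p
}
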