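#' Plot a gene-pair loop in its two-gene plane
#'
#' Scatter of every sample's (lead, lag) expression coordinates coloured by
#' time rank, with the path of the per-time medians drawn through them. A
#' genuine phase-shifted pair traces a loop; unrelated genes collapse onto a
#' line or blob.
#'
#' @param data Long expression tibble (typically baseline-centred).
#' @param lead_gene,lag_gene The gene pair.
#' @return A ggplot object.
#' @export
plot_loop_pair <- function(data, lead_gene, lag_gene) {
  pts <- pair_coordinates(data, lead_gene, lag_gene) |>
    dplyr::mutate(time_rank = match(.data$time, sort(unique(.data$time))) - 1L)
  path <- pts |>
    dplyr::summarise(x = stats::median(.data$x), y = stats::median(.data$y),
                     .by = "time_rank") |>
    dplyr::arrange(.data$time_rank)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = path, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$time_rank), size = 2) +
    ggplot2::scale_colour_viridis_c(name = "time rank") +
    ggplot2::labs(x = paste0(lead_gene, " (log2, centred)"),
                  y = paste0(lag_gene, " (log2, centred)"),
                  title = paste(lead_gene, "vs", lag_gene)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted loop's polar geometry
#'
#' Left-to-right reading of a `polar_loop`: unwrapped angle against time
#' rank, annotated with the Pearson correlation. Angle tracking time linearly
#' is what qualifies the pair as a usable map of the trajectory.
#'
#' @param object A `polar_loop` from [polar_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polar_loop <- function(object, ...) {
  pts <- tibble::as_tibble(object$points)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_rank,
                                    y = .data$angle_unwrapped)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$radius), size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "time rank", y = "unwrapped angle (degrees)",
      title = sprintf("%s / %s loop: angle vs time (rho = %.2f)",
                      object$lead_gene, object$lag_gene,
                      object$angle_time_rho)
    ) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a prediction run
#'
#' @param object A `stage_prediction`.
#' @param ... Unused.
#' @return A ggplot object (truth on rows, prediction on columns).
#' @export
autoplot.stage_prediction <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Accuracy %.0f%% (n = %d)",
                                  100 * object$accuracy, object$n),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
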