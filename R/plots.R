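#' Plot a longitudinal metrics series
#'
#' Line plot of density, centralization and in-degree centralization by week,
#' faceted by relation, with day and night shifts as separate series --
#' mirroring the standard metrics-over-time display.
#'
#' @param object A `metrics_series` from [build_series()].
#' @param metrics Which metric columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_series
#' @export
autoplot.metrics_series <- function(object,
                                    metrics = c("density_pct",
                                                "centralization_pct",
                                                "in_degree_centralization_pct"),
                                    ...) {
  long <- object |>
    dplyr::select("week", "shift", "relation", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$week, y = .data$value,
                               colour = .data$shift, linetype = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$relation)) +
    ggplot2::labs(x = "Study week", y = "Percentage",
                  colour = "Shift", linetype = "Metric") +
    ggplot2::theme_minimal()
}

#' Boxplots of QAP correlations by relation pair and shift
#'
#' The six-boxplot display: distribution of observed matrix correlations per
#' relation pair, day and night shifts side by side, showing median, IQR and
#' range.
#'
#' @param object A `qap_panel` from [qap_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qap_panel
#' @export
autoplot.qap_panel <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pair, y = .data$r_obs,
                               fill = .data$shift)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Relation pair", y = "QAP correlation r", fill = "Shift") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Draw a sociogram specification
#'
#' Node-link rendering of an exported sociogram: node size proportional to
#' in-degree centrality, edge width proportional to reported frequency,
#' isolates placed apart from the connected component.
#'
#' @param object A `sociogram_spec` from [export_sociogram()].
#' @param label Draw person-id labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sociogram_spec
#' @export
autoplot.sociogram_spec <- function(object, label = TRUE, ...) {
  nodes <- object$nodes
  edges <- object$edges |>
    dplyr::left_join(nodes[c("id", "x", "y")], by = c(source = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes[c("id", "x", "y")], by = c(target = "id")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$width),
      colour = "grey55", alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$role, shape = .data$isolate)
    ) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_linewidth_identity() +
    ggplot2::labs(title = sprintf("%s — %s", object$shift_id %||% "",
                                  object$relation),
                  colour = "Role", shape = "Isolate") +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      size = 2.5, vjust = -1.2
    )
  }
  p
}
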