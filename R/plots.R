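#' Plot the accepted-edge count across the threshold sweep
#'
#' @param object A `grn_edge_curve` from [edges_vs_threshold()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.grn_edge_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$edge_count)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(theta), y = "Accepted interactions",
                  title = "Edges versus acceptance threshold") +
    ggplot2::theme_minimal()
}

#' @export
plot.grn_edge_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot a regulatory network
#'
#' Draws nodes on a deterministic circular layout with arrows from regulator
#' to target; edge labels carry the interaction strength.
#'
#' @param object A `grn`.
#' @param label_strength Print strengths on the edges.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.grn <- function(object, label_strength = TRUE, ...) {
  nodes <- sort(object$nodes)
  angle <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[seq_along(nodes)]
  layout <- tibble::tibble(gene = nodes, x = cos(angle), y = sin(angle))
  e <- object$edges
  seg <- dplyr::mutate(
    e,
    x = layout$x[match(.data$regulator, layout$gene)],
    y = layout$y[match(.data$regulator, layout$gene)],
    xend = layout$x[match(.data$target, layout$gene)],
    yend = layout$y[match(.data$target, layout$gene)])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches"), type = "closed"),
      colour = "grey40") +
    ggplot2::geom_label(data = layout, ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(title = sprintf("Regulatory network: %s (theta = %s)",
                                  object$condition_label, format(object$theta))) +
    ggplot2::theme_void()
  if (label_strength && nrow(seg)) {
    p <- p + ggplot2::geom_text(
      data = seg,
      ggplot2::aes(x = (.data$x + .data$xend) / 2, y = (.data$y + .data$yend) / 2,
                   label = sprintf("%.3f", .data$strength)),
      size = 3, vjust = -0.5)
  }
  p
}

#' @export
plot.grn <- function(x, ...) print(autoplot(x, ...))
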