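#' Plot a causal graph
#'
#' Nodes on a circle; one curved edge per link, coloured by lag. Directed
#' links end in an arrow; unoriented and conflicting contemporaneous links
#' are drawn without arrowheads (dashed when in conflict). Multiple lags
#' between the same ordered pair are drawn with different curvature.
#'
#' @param object A `causal_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot causal_graph
#' @export
autoplot.causal_graph <- function(object, ...) {
  vn <- object$var_names
  n <- length(vn)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes <- tibble::tibble(name = vn, x = cos(theta), y = sin(theta))
  lk <- object$links
  if (nrow(lk) > 0) {
    lk <- dplyr::left_join(lk, nodes, by = c("source" = "name")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nodes, by = c("sink" = "name")) |>
      dplyr::rename(x1 = "x", y1 = "y") |>
      dplyr::group_by(.data$source, .data$sink) |>
      dplyr::mutate(curv = 0.15 + 0.12 * (dplyr::row_number() - 1)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        # trim endpoints so arrowheads sit outside the node labels
        x0 = .data$x0 + 0.12 * (.data$x1 - .data$x0),
        y0 = .data$y0 + 0.12 * (.data$y1 - .data$y0),
        x1 = .data$x1 - 0.12 * (.data$x1 - .data$x0),
        y1 = .data$y1 - 0.12 * (.data$y1 - .data$y0)
      )
  }
  p <- ggplot2::ggplot()
  if (nrow(lk) > 0) {
    directed <- lk[lk$orientation == "directed", , drop = FALSE]
    undirected <- lk[lk$orientation != "directed", , drop = FALSE]
    for (r in seq_len(nrow(directed))) {
      p <- p + ggplot2::geom_curve(
        data = directed[r, ],
        ggplot2::aes(
          x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          colour = factor(.data$lag)
        ),
        curvature = directed$curv[r],
        arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"), type = "closed"),
        linewidth = 0.5
      )
    }
    for (r in seq_len(nrow(undirected))) {
      p <- p + ggplot2::geom_curve(
        data = undirected[r, ],
        ggplot2::aes(
          x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          colour = factor(.data$lag)
        ),
        curvature = undirected$curv[r],
        linetype = if (undirected$orientation[r] == "conflict") "dashed" else "solid",
        linewidth = 0.5
      )
    }
  }
  p +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 3
    ) +
    ggplot2::scale_colour_viridis_d(name = "lag (days)") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}
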