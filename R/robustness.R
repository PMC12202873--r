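#' Link-persistence analysis over a hyperparameter grid
#'
#' Reruns the full discovery engine once per cell of the
#' `tau_grid x alpha_grid` grid (default 10 x 3 = 30 cells) and scores, for
#' every link ever seen, the fraction of cells in which a link with the same
#' (source, sink, lag) identity survives the MCI stage. Orientation is
#' ignored when matching -- contemporaneous orientation can flip across
#' hyperparameters -- and the denominator is always the full grid size, even
#' for links whose lag exceeds some cells' tau_max (such cells can never
#' contain the link); `max_attainable` reports the reachable ceiling for
#' transparency.
#'
#' @param panel A (preprocessed) `ts_panel`.
#' @param tau_grid Maximum-lag grid (default 5:14).
#' @param alpha_grid Significance-level grid (default 0.05, 0.01, 0.001).
#' @return A tibble sorted by descending persistence then (source, sink,
#'   lag): `source`, `sink`, `lag`, `n_found`, `n_cells`, `persistence`,
#'   `max_attainable`; per-cell detail (tau_max, alpha, found) in the
#'   `detail` attribute.
#' @export
link_persistence <- function(panel, tau_grid = 5:14,
                             alpha_grid = c(0.05, 0.01, 0.001)) {
  stopifnot(length(tau_grid) > 0, length(alpha_grid) > 0)
  cells <- tidyr::expand_grid(tau_max = tau_grid, alpha = alpha_grid)
  found <- purrr::map_dfr(seq_len(nrow(cells)), function(r) {
    g <- run_pcmciplus(panel,
      tau_max = cells$tau_max[r], alpha = cells$alpha[r]
    )
    lk <- g$links
    if (nrow(lk) == 0) {
      return(tibble::tibble(
        source = character(), sink = character(), lag = integer(),
        tau_max = integer(), alpha = numeric()
      ))
    }
    # canonicalise lag-0 pairs so orientation does not affect matching
    swap <- lk$lag == 0L & lk$source > lk$sink
    tmp <- lk$source[swap]
    lk$source[swap] <- lk$sink[swap]
    lk$sink[swap] <- tmp
    lk <- unique(lk[, c("source", "sink", "lag")])
    lk$tau_max <- cells$tau_max[r]
    lk$alpha <- cells$alpha[r]
    lk
  })
  m <- nrow(cells)
  if (nrow(found) == 0) {
    out <- tibble::tibble(
      source = character(), sink = character(), lag = integer(),
      n_found = integer(), n_cells = integer(),
      persistence = numeric(), max_attainable = numeric()
    )
    attr(out, "detail") <- found
    return(out)
  }
  out <- found |>
    dplyr::count(.data$source, .data$sink, .data$lag, name = "n_found") |>
    dplyr::mutate(
      n_cells = m,
      persistence = .data$n_found / m,
      max_attainable = vapply(
        .data$lag,
        function(l) sum(cells$tau_max >= max(l, 1L)) / m, numeric(1)
      )
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$persistence), .data$source, .data$sink, .data$lag
    )
  attr(out, "detail") <- found
  out
}

#' Persistence heat map
#'
#' Tile plot of link presence per grid cell, one facet per link.
#'
#' @param records Output of [link_persistence()] (its `detail` attribute is
#'   used).
#' @return A ggplot object.
#' @export
plot_persistence <- function(records) {
  detail <- attr(records, "detail")
  stopifnot(!is.null(detail))
  detail$link <- paste0(
    detail$source, " %->% ", detail$sink, " (lag ", detail$lag, ")"
  )
  ggplot2::ggplot(
    detail,
    ggplot2::aes(
      x = factor(.data$tau_max),
      y = factor(.data$alpha)
    )
  ) +
    ggplot2::geom_tile(fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~link) +
    ggplot2::labs(
      x = "maximum lag", y = "significance level",
      title = "Cells in which each link is recovered"
    )
}
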