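#' Pairwise Granger-causality F-test
#'
#' Compares two nested OLS models for the sink series: the restricted model
#' regresses \eqn{y_t} on an intercept and its own lags
#' \eqn{y_{t-1}, ..., y_{t-L}}; the full model adds the source's lags
#' \eqn{x_{t-1}, ..., x_{t-L}}. Both are fitted on the identical row set
#' (rows lost to the longest lag dropped once), so the residual sums of
#' squares are nested and
#' \deqn{F = \frac{(RSS_r - RSS_f)/L}{RSS_f/(n - k)},\quad k = 2L + 1,}
#' with the p-value from the F(L, n - k) distribution. A small p-value says
#' the source's history improves prediction of the sink beyond the sink's
#' own history.
#'
#' @param panel A `ts_panel`.
#' @param source,sink Variable name or column index (excluding the date
#'   column); must differ.
#' @param L Lag order (>= 1).
#' @return A one-row tibble: `source`, `sink`, `lag_order`, `f_stat`,
#'   `p_value`, `rss_restricted`, `rss_full`, `n_used`, `q`, `k`.
#' @export
granger_f_test <- function(panel, source, sink, L) {
  validate_ts_panel(panel)
  vars <- panel_vars(panel)
  src <- if (is.character(source)) source else vars[source]
  snk <- if (is.character(sink)) sink else vars[sink]
  stopifnot(src %in% vars, snk %in% vars, src != snk, L >= 1)
  x <- panel[[src]]
  y <- panel[[snk]]
  n <- length(y)
  if (n - L <= 2 * L + 1) stop("series too short for lag order L", call. = FALSE)
  rows <- (L + 1):n
  ylags <- sapply(seq_len(L), function(i) y[rows - i])
  xlags <- sapply(seq_len(L), function(i) x[rows - i])
  yy <- y[rows]
  Xr <- cbind(1, ylags)
  Xf <- cbind(Xr, xlags)
  fr <- stats::lm.fit(Xr, yy)
  ff <- stats::lm.fit(Xf, yy)
  if (ff$rank < ncol(Xf) || fr$rank < ncol(Xr)) {
    stop("rank-deficient regression", call. = FALSE)
  }
  rss_r <- sum(fr$residuals^2)
  rss_f <- sum(ff$residuals^2)
  k <- 2L * L + 1L
  n_used <- length(yy)
  fstat <- ((rss_r - rss_f) / L) / (rss_f / (n_used - k))
  tibble::tibble(
    source = src, sink = snk, lag_order = as.integer(L),
    f_stat = fstat,
    p_value = stats::pf(fstat, L, n_used - k, lower.tail = FALSE),
    rss_restricted = rss_r, rss_full = rss_f,
    n_used = n_used, q = as.integer(L), k = k
  )
}

#' Granger scan of all sources into one sink
#'
#' Runs [granger_f_test()] for every source variable other than the sink at
#' every requested lag order, in deterministic (source order, then lag)
#' order — the validation sweep run with the acquisition proxy as the sink.
#'
#' @param panel A `ts_panel`.
#' @param sink Sink variable name or index.
#' @param lags Integer vector of lag orders (default 1:7).
#' @return A tibble with one row per (source, lag order).
#' @export
granger_scan <- function(panel, sink, lags = 1:7) {
  vars <- panel_vars(panel)
  snk <- if (is.character(sink)) sink else vars[sink]
  sources <- setdiff(vars, snk)
  purrr::map_dfr(sources, function(src) {
    purrr::map_dfr(lags, function(L) granger_f_test(panel, src, snk, L))
  })
}
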