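#' Default seasonal periods for daily count panels
#'
#' Calendar periods, in days, at which daily social and administrative count
#' series typically cycle: day-of-week structure (1, 2, 3, 5, 7), monthly
#' effects (30, 31, 365.25/12) and the annual cycle (365.25).
#'
#' @return A numeric vector of nine periods.
#' @export
default_periods <- function() {
  c(1, 2, 3, 5, 7, 30, 31, 365.25 / 12, 365.25)
}

# Harmonic design matrix: intercept + one sine/cosine pair per period > 1.
# A period equal to the sampling interval aliases to a constant, so period 1
# contributes only the intercept; the sine column at period 2 (Nyquist) is
# identically zero on an integer grid and is dropped.
harmonic_design <- function(n, periods) {
  tt <- seq_len(n)
  cols <- list(intercept = rep(1, n))
  for (p in periods) {
    if (p <= 1) next
    w <- 2 * pi / p
    cols[[paste0("cos_", p)]] <- cos(w * tt)
    s <- sin(w * tt)
    if (max(abs(s)) > 1e-8) cols[[paste0("sin_", p)]] <- s
  }
  do.call(cbind, cols)
}

#' Seasonal adjustment by harmonic regression
#'
#' Subtracts, per variable, the least-squares fit of an intercept plus one
#' sine/cosine pair per period. Harmonic regression handles non-integer
#' periods (365.25/12, 365.25) naturally and is an orthogonal projection, so
#' applying it twice changes nothing.
#'
#' @param panel A `ts_panel`.
#' @param periods Seasonal periods in days (positive; each must be < T).
#' @return A `ts_panel` of residual series, same shape and dates.
#' @export
seasonal_adjust <- function(panel, periods = default_periods()) {
  validate_ts_panel(panel)
  stopifnot(length(periods) > 0, all(periods > 0))
  n <- nrow(panel)
  if (any(periods >= n)) {
    stop("period exceeds series length", call. = FALSE)
  }
  X <- harmonic_design(n, periods)
  Y <- panel_matrix(panel)
  fit <- stats::lm.fit(X, Y)
  resid <- Y - X %*% fit$coefficients
  out <- panel
  out[panel_vars(panel)] <- tibble::as_tibble(resid)
  out
}

#' Detrend by a local-linear smooth
#'
#' Estimates a slowly varying trend per variable with a locally weighted
#' linear smoother (bandwidth in days) and subtracts it; the residual is then
#' centred so the output is zero-mean to numerical tolerance.
#'
#' @param panel A `ts_panel` with at least 30 rows.
#' @param bandwidth Smoother window, days; the smoother span is
#'   `bandwidth / T` (capped at 1).
#' @return A `ts_panel` of detrended, centred series.
#' @export
detrend <- function(panel, bandwidth = 365) {
  validate_ts_panel(panel)
  n <- nrow(panel)
  if (n < 30) stop("detrend needs T >= 30", call. = FALSE)
  span <- min(1, bandwidth / n)
  tt <- seq_len(n)
  out <- panel
  for (v in panel_vars(panel)) {
    sm <- stats::lowess(tt, panel[[v]], f = span, iter = 0)$y
    r <- panel[[v]] - sm
    out[[v]] <- r - mean(r)
  }
  out
}

#' Full preprocessing: seasonal adjustment then detrending
#'
#' @inheritParams seasonal_adjust
#' @inheritParams detrend
#' @return A `ts_panel` ready for stationarity gating and causal discovery.
#' @export
preprocess_panel <- function(panel, periods = default_periods(),
                             bandwidth = 365) {
  detrend(seasonal_adjust(panel, periods), bandwidth)
}

# MacKinnon (1994) response-surface constants for the constant-only
# (A)DF t distribution, one I(1) variable: p = pnorm(polynomial(stat)).
.adf_tau_star <- -1.61
.adf_tau_min <- -18.83
.adf_tau_max <- 2.74
.adf_small_p <- c(2.1659, 1.4412, 0.038269)
.adf_large_p <- c(1.7339, 0.93202, -0.12745, -0.010368)

adf_pvalue <- function(stat) {
  if (stat > .adf_tau_max) return(1)
  if (stat < .adf_tau_min) return(0)
  co <- if (stat <= .adf_tau_star) .adf_small_p else .adf_large_p
  stats::pnorm(sum(co * stat^(seq_along(co) - 1)))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the differenced series on an intercept, the lagged level and
#' lagged differences, with the lag order chosen by AIC up to
#' `floor(12 * (T/100)^(1/4))`. Small p-values reject the unit root, i.e.
#' support stationarity; the p-value comes from the MacKinnon (1994)
#' response-surface approximation for the constant-only case. No
#' deterministic-trend term is included, on the assumption that the series
#' has already been detrended.
#'
#' @param x Numeric series, length >= 50, not constant.
#' @param max_lag Largest augmentation lag tried; default the Schwert rule.
#' @return An object of class `htest` with `statistic`, `p.value` and the
#'   selected lag order in `parameter`.
#' @export
adf_test <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 50) stop("adf_test needs length >= 50", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("degenerate input: constant series", call. = FALSE)
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, n - 10L)
  dx <- diff(x)
  fit_k <- function(k, align) {
    # align: first usable index of dx so every candidate sees the same rows
    idx <- (align + 1):length(dx)
    y <- dx[idx]
    X <- cbind(1, x[idx]) # intercept, lagged level
    if (k > 0) {
      D <- sapply(seq_len(k), function(i) dx[idx - i])
      X <- cbind(X, D)
    }
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    list(fit = f, rss = rss, n = length(y), k = k, X = X, y = y)
  }
  # AIC over a common sample aligned at max_lag, then refit the winner on the
  # longest sample its own lag order allows
  aics <- vapply(0:max_lag, function(k) {
    f <- fit_k(k, max_lag)
    f$n * log(f$rss / f$n) + 2 * (k + 2)
  }, numeric(1))
  k_best <- (0:max_lag)[which.min(aics)]
  f <- fit_k(k_best, k_best)
  co <- f$fit$coefficients
  resid <- f$fit$residuals
  dfree <- f$n - length(co)
  sigma2 <- sum(resid^2) / dfree
  XtX_inv <- chol2inv(chol(crossprod(f$X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  stat <- unname(co[2] / se)
  structure(
    list(
      statistic = c(ADF = stat),
      parameter = c(lag_order = k_best),
      p.value = adf_pvalue(stat),
      method = "Augmented Dickey-Fuller test (constant, MacKinnon p-value)",
      alternative = "stationary",
      data.name = deparse(substitute(x))
    ),
    class = "htest"
  )
}

# KPSS level-stationarity critical values (Kwiatkowski et al. 1992, Table 1)
.kpss_crit <- c(0.347, 0.463, 0.574, 0.739)
.kpss_p <- c(0.10, 0.05, 0.025, 0.01)

kpss_bracket <- function(stat) {
  if (stat < .kpss_crit[1]) return("> 0.1")
  if (stat < .kpss_crit[2]) return("0.05-0.1")
  if (stat < .kpss_crit[3]) return("0.025-0.05")
  if (stat < .kpss_crit[4]) return("0.01-0.025")
  "< 0.01"
}

#' KPSS level-stationarity test
#'
#' Null hypothesis: the series is level-stationary; large statistics (small
#' p) reject it. The long-run variance uses a Bartlett/Newey-West kernel with
#' the Hobijn et al. (1998) automatic bandwidth. Because only four critical
#' values are tabulated, the p-value is reported primarily as a bracket
#' (`"> 0.1"` through `"< 0.01"`); the point `p.value` is linearly
#' interpolated inside the table and clamped to [0.01, 0.1] outside it.
#'
#' @param x Numeric series, length >= 50, not constant.
#' @param lags `"auto"` for the automatic bandwidth, or a non-negative
#'   integer.
#' @return An `htest` with `statistic`, interpolated `p.value`, and the
#'   bracket in `$bracket`.
#' @export
kpss_test <- function(x, lags = "auto") {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 50) stop("kpss_test needs length >= 50", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("degenerate input: constant series", call. = FALSE)
  resid <- x - mean(x)
  if (identical(lags, "auto")) {
    covlags <- as.integer(n^(2 / 9))
    s0 <- sum(resid^2) / n
    s1 <- 0
    for (i in seq_len(covlags)) {
      rp <- sum(resid[(i + 1):n] * resid[1:(n - i)]) / (n / 2)
      s0 <- s0 + rp
      s1 <- s1 + i * rp
    }
    gamma_hat <- 1.1447 * abs(s1 / s0)^(2 / 3)
    lags <- as.integer(gamma_hat * n^(1 / 3))
  }
  lags <- min(as.integer(lags), n - 1L)
  s_hat <- sum(resid^2)
  if (lags > 0) {
    for (i in seq_len(lags)) {
      s_hat <- s_hat + 2 * sum(resid[(i + 1):n] * resid[1:(n - i)]) *
        (1 - i / (lags + 1))
    }
  }
  sigma2 <- s_hat / n
  eta <- sum(cumsum(resid)^2) / n^2
  stat <- eta / sigma2
  p <- stats::approx(.kpss_crit, .kpss_p,
    xout = stat, rule = 2
  )$y
  structure(
    list(
      statistic = c(KPSS = stat),
      parameter = c(truncation_lag = lags),
      p.value = p,
      bracket = kpss_bracket(stat),
      method = "KPSS test for level stationarity (Newey-West, auto bandwidth)",
      alternative = "nonstationary",
      data.name = deparse(substitute(x))
    ),
    class = "htest"
  )
}

#' Stationarity report for a panel
#'
#' Runs [adf_test()] and [kpss_test()] on every variable and applies the
#' joint gate: a series is verdicted stationary when the ADF test rejects the
#' unit root (`adf_p < alpha`) and the KPSS test fails to reject level
#' stationarity (bracket `"> 0.1"`). Series failing the gate are flagged, not
#' dropped.
#'
#' @param panel A preprocessed `ts_panel`.
#' @param alpha ADF rejection level (default 0.05).
#' @return A tibble with one row per variable: `variable`, `adf_stat`,
#'   `adf_p`, `kpss_stat`, `kpss_p`, `kpss_p_bracket`, `stationary`.
#' @export
stationarity_report <- function(panel, alpha = 0.05) {
  validate_ts_panel(panel)
  purrr::map_dfr(panel_vars(panel), function(v) {
    a <- adf_test(panel[[v]])
    k <- kpss_test(panel[[v]])
    tibble::tibble(
      variable = v,
      adf_stat = unname(a$statistic),
      adf_p = a$p.value,
      kpss_stat = unname(k$statistic),
      kpss_p = k$p.value,
      kpss_p_bracket = k$bracket,
      stationary = a$p.value < alpha & k$bracket == "> 0.1"
    )
  })
}
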