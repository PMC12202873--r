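#' Partial-correlation conditional-independence test
#'
#' The dependence measure used throughout the discovery engine: `x` and `y`
#' are each regressed on an intercept plus the conditioning columns `z` by
#' least squares, and `rho` is the Pearson correlation of the two residual
#' vectors. The two-sided p-value comes from the t statistic
#' \eqn{\rho \sqrt{(n - |Z| - 2)/(1 - \rho^2)}} on \eqn{n - |Z| - 2} degrees
#' of freedom (intercept counted); \eqn{|\rho| = 1} yields p = 0. The sign of
#' `rho` reads as the direction of the association.
#'
#' @param x,y Numeric vectors of equal length.
#' @param z Optional conditioning set: a numeric matrix or data frame with
#'   one column per conditioning variable (may be `NULL` or zero-column).
#' @return A one-row tibble of class `ci_test`: `rho`, `p_value`, `n_eff`,
#'   `df`, `n_cond`.
#' @examples
#' x <- rnorm(200); z <- rnorm(200); y <- 0.5 * z + rnorm(200)
#' parcorr_test(x, y, z)
#' @export
parcorr_test <- function(x, y, z = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(z)) {
    Z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    Z <- as.matrix(z)
    stopifnot(nrow(Z) == n)
    storage.mode(Z) <- "double"
  }
  if (n <= ncol(Z) + 2) {
    stop("n_eff must exceed |Z| + 2", call. = FALSE)
  }
  res <- .parcorr(cbind(x, y), Z)
  tibble::new_tibble(
    tibble::tibble(
      rho = res[1], p_value = res[2],
      n_eff = n, df = as.integer(res[3]), n_cond = ncol(Z)
    ),
    class = "ci_test"
  )
}

# Fast core shared with the discovery engine: XY is an n x 2 matrix, Z the
# conditioning columns (no intercept). Returns c(rho, p, df).
.parcorr <- function(XY, Z) {
  n <- nrow(XY)
  X <- cbind(1, Z)
  f <- stats::lm.fit(X, XY)
  if (f$rank < ncol(X)) {
    stop("degenerate conditioning set: rank-deficient regression", call. = FALSE)
  }
  R <- f$residuals
  vx <- sum(R[, 1]^2)
  vy <- sum(R[, 2]^2)
  if (vx <= n * 1e-24 || vy <= n * 1e-24) {
    stop("degenerate conditioning set: zero residual variance", call. = FALSE)
  }
  rho <- sum(R[, 1] * R[, 2]) / sqrt(vx * vy)
  rho <- max(-1, min(1, rho))
  dfree <- n - ncol(Z) - 2
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt(dfree / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), dfree)
  }
  c(rho, p, dfree)
}
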