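# Shared generators for test panels and small SCMs.

make_panel <- function(values, start = as.Date("2015-01-01")) {
  values <- as.data.frame(values)
  as_ts_panel(dplyr::bind_cols(
    tibble::tibble(date = seq(start, by = "day", length.out = nrow(values))),
    values
  ))
}

white_noise_panel <- function(n_days, n_vars, seed,
                              names = paste0("V", seq_len(n_vars))) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_days * n_vars), n_days, n_vars)
    colnames(vals) <- names
    make_panel(vals)
  })
}

# two variables, planted source_{t-lag} -> sink with weight c, AR(1) noise
planted_pair_spec <- function(c = 0.5, lag = 1, auto = 0.4) {
  scm_spec(
    tibble::tibble(source = 1L, sink = 2L, lag = as.integer(lag), coeff = c),
    n_vars = 2, auto_coeffs = auto, var_names = c("X", "Y")
  )
}

# sample partial correlation of x, y given Z via the inverse of the sample
# covariance matrix -- the closed-form oracle for the residual-based rho
parcorr_precision_oracle <- function(x, y, Z) {
  S <- stats::cov(cbind(x, y, Z))
  Om <- solve(S)
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# recursive partial-correlation formula, conditioning variables peeled one
# at a time: r_{xy.Zw} = (r_{xy.Z} - r_{xw.Z} r_{yw.Z}) / sqrt((1-r_{xw.Z}^2)(1-r_{yw.Z}^2))
parcorr_recursive_oracle <- function(M, a, b, cond) {
  if (length(cond) == 0) {
    return(stats::cor(M[, a], M[, b]))
  }
  w <- cond[length(cond)]
  rest <- cond[-length(cond)]
  r_ab <- parcorr_recursive_oracle(M, a, b, rest)
  r_aw <- parcorr_recursive_oracle(M, a, w, rest)
  r_bw <- parcorr_recursive_oracle(M, b, w, rest)
  (r_ab - r_aw * r_bw) / sqrt((1 - r_aw^2) * (1 - r_bw^2))
}
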