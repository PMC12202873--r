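#' Specify a linear-Gaussian structural-causal time-series model
#'
#' An `scm_spec` is the ground-truth data-generating process used throughout
#' the test harness: a set of lagged and contemporaneous linear links between
#' variables, an AR(1) self-coefficient per variable, Gaussian innovations,
#' and optional deterministic seasonality and trend contamination. The
#' contemporaneous (lag-0) sub-graph must be acyclic and the lagged system
#' stable (companion-matrix spectral radius < 1).
#'
#' @param links Tibble/data frame with columns `source`, `sink` (integer
#'   variable indices), `lag` (integer >= 0) and `coeff` (real). No lag-0
#'   self-links.
#' @param n_vars Number of variables N.
#' @param auto_coeffs AR(1) self-coefficient per variable (recycled).
#' @param noise_scales Innovation standard deviation per variable (recycled,
#'   all >= 0).
#' @param var_names Variable labels (unique, length `n_vars`).
#' @param seasonal_amplitudes Matrix `n_vars` x `length(periods)` of cosine
#'   amplitudes, or a single number recycled; 0 disables.
#' @param periods Seasonal periods, in days, for the amplitude columns.
#' @param trend_slopes Linear trend slope per variable, units per day.
#' @return An object of class `scm_spec`.
#' @seealso [make_random_scm()], [study_mimic_spec()], [simulate_panel()]
#' @export
scm_spec <- function(links, n_vars,
                     auto_coeffs = 0,
                     noise_scales = 1,
                     var_names = paste0("V", seq_len(n_vars)),
                     seasonal_amplitudes = 0,
                     periods = default_periods(),
                     trend_slopes = 0) {
  links <- tibble::as_tibble(links)
  if (nrow(links) == 0) {
    links <- tibble::tibble(
      source = integer(), sink = integer(),
      lag = integer(), coeff = numeric()
    )
  }
  stopifnot(all(c("source", "sink", "lag", "coeff") %in% names(links)))
  links$source <- as.integer(links$source)
  links$sink <- as.integer(links$sink)
  links$lag <- as.integer(links$lag)
  var_names <- as.vector(var_names, mode = "character")
  stopifnot(
    n_vars >= 1, length(var_names) == n_vars, !anyDuplicated(var_names),
    all(links$source >= 1), all(links$source <= n_vars),
    all(links$sink >= 1), all(links$sink <= n_vars),
    all(links$lag >= 0), all(noise_scales >= 0)
  )
  if (any(links$lag == 0 & links$source == links$sink)) {
    stop("no self-link at lag 0 is allowed", call. = FALSE)
  }
  auto_coeffs <- rep_len(auto_coeffs, n_vars)
  noise_scales <- rep_len(noise_scales, n_vars)
  trend_slopes <- rep_len(trend_slopes, n_vars)
  if (is.matrix(seasonal_amplitudes)) {
    stopifnot(
      nrow(seasonal_amplitudes) == n_vars,
      ncol(seasonal_amplitudes) == length(periods)
    )
  } else {
    seasonal_amplitudes <- matrix(
      rep_len(seasonal_amplitudes, n_vars * length(periods)),
      nrow = n_vars
    )
  }
  stopifnot(all(seasonal_amplitudes >= 0), all(periods > 0))
  spec <- structure(
    list(
      n_vars = as.integer(n_vars),
      var_names = var_names,
      links = links,
      auto_coeffs = auto_coeffs,
      noise_scales = noise_scales,
      seasonal_amplitudes = seasonal_amplitudes,
      periods = periods,
      trend_slopes = trend_slopes
    ),
    class = "scm_spec"
  )
  topo_order_lag0(spec) # errors if the contemporaneous sub-graph is cyclic
  sr <- spectral_radius(spec)
  if (sr >= 1) {
    stop(
      sprintf("unstable configuration: companion spectral radius %.3f >= 1", sr),
      call. = FALSE
    )
  }
  spec
}

#' @export
print.scm_spec <- function(x, ...) {
  cat(
    "Linear-Gaussian SCM: ", x$n_vars, " variables, ",
    nrow(cross_links(x)), " cross-links, max lag ", max(c(1L, x$links$lag)),
    ", spectral radius ", signif(spectral_radius(x), 3), "\n",
    sep = ""
  )
  print(x$links, ...)
  invisible(x)
}

cross_links <- function(spec) {
  dplyr::filter(spec$links, .data$source != .data$sink)
}

# Topological order of the lag-0 sub-graph; errors on a cycle.
topo_order_lag0 <- function(spec) {
  n <- spec$n_vars
  l0 <- dplyr::filter(spec$links, .data$lag == 0L)
  order <- integer(0)
  indeg <- integer(n)
  for (j in seq_len(n)) indeg[j] <- sum(l0$sink == j)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    free <- remaining[indeg[remaining] == 0L]
    if (length(free) == 0) {
      stop("contemporaneous links must form an acyclic graph", call. = FALSE)
    }
    v <- free[1]
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
    out <- l0$sink[l0$source == v]
    for (j in out) indeg[j] <- indeg[j] - 1L
  }
  order
}

# Reduced-form lag matrices: X_t = B0 X_t + sum_tau A_tau X_{t-tau} + eps
# => X_t = (I - B0)^{-1} (sum A_tau X_{t-tau} + eps). Stability is judged on
# the companion form of the reduced lag polynomial.
lag_matrices <- function(spec) {
  n <- spec$n_vars
  p <- max(c(1L, spec$links$lag))
  B0 <- matrix(0, n, n)
  A <- replicate(p, matrix(0, n, n), simplify = FALSE)
  for (r in seq_len(nrow(spec$links))) {
    lk <- spec$links[r, ]
    if (lk$lag == 0L) {
      B0[lk$sink, lk$source] <- B0[lk$sink, lk$source] + lk$coeff
    } else {
      A[[lk$lag]][lk$sink, lk$source] <- A[[lk$lag]][lk$sink, lk$source] + lk$coeff
    }
  }
  for (j in seq_len(n)) A[[1]][j, j] <- A[[1]][j, j] + spec$auto_coeffs[j]
  list(B0 = B0, A = A, p = p)
}

#' Companion-form spectral radius of an SCM
#'
#' Largest eigenvalue modulus of the companion matrix of the reduced-form
#' lagged system; the process is (covariance-)stable iff this is < 1.
#'
#' @param spec An `scm_spec`.
#' @return A single non-negative number.
#' @export
spectral_radius <- function(spec) {
  m <- lag_matrices(spec)
  n <- spec$n_vars
  inv <- solve(diag(n) - m$B0)
  comp <- matrix(0, n * m$p, n * m$p)
  for (tau in seq_len(m$p)) {
    comp[seq_len(n), (tau - 1) * n + seq_len(n)] <- inv %*% m$A[[tau]]
  }
  if (m$p > 1) {
    comp[n + seq_len(n * (m$p - 1)), seq_len(n * (m$p - 1))] <-
      diag(n * (m$p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Draw a random stable SCM
#'
#' Samples cross-links at a given density with coefficients uniform on
#' `coeff_range` (random sign if the range is positive). Contemporaneous
#' links are only drawn from later to earlier positions of a shuffled
#' topological order, so lag-0 acyclicity holds by construction. Specs whose
#' companion matrix is unstable are resampled with shrunk coefficients a
#' bounded number of times.
#'
#' @param n_vars Number of variables (>= 2).
#' @param cross_density Probability that any (source, sink, lag) cross-link
#'   slot carries a link.
#' @param lag_max Largest lag considered (>= 0).
#' @param coeff_range Length-2 interval inside (-1, 1) for coefficient
#'   magnitudes.
#' @param auto_coeffs,noise_scales Passed to [scm_spec()].
#' @param seed Integer seed; same seed, same spec.
#' @param max_tries Stability resampling attempts before giving up.
#' @return An `scm_spec`.
#' @export
make_random_scm <- function(n_vars, cross_density, lag_max, seed,
                            coeff_range = c(0.1, 0.5),
                            auto_coeffs = 0.4, noise_scales = 1,
                            max_tries = 25L) {
  stopifnot(
    n_vars >= 2, cross_density >= 0, cross_density <= 1, lag_max >= 0,
    length(coeff_range) == 2, all(abs(coeff_range) < 1)
  )
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      shrink <- 0.8^(try - 1)
      order <- sample(n_vars)
      rows <- list()
      for (j in seq_len(n_vars)) {
        for (i in seq_len(n_vars)) {
          for (lag in 0:lag_max) {
            if (i == j) next # self-dependence handled by auto_coeffs
            if (lag == 0L && which(order == i) >= which(order == j)) next
            if (stats::runif(1) < cross_density) {
              coeff <- stats::runif(1, coeff_range[1], coeff_range[2]) * shrink
              if (all(coeff_range >= 0)) coeff <- coeff * sample(c(-1, 1), 1)
              rows[[length(rows) + 1]] <-
                tibble::tibble(source = i, sink = j, lag = lag, coeff = coeff)
            }
          }
        }
      }
      links <- dplyr::bind_rows(rows)
      spec <- tryCatch(
        scm_spec(links, n_vars,
          auto_coeffs = auto_coeffs * shrink,
          noise_scales = noise_scales
        ),
        error = function(e) NULL
      )
      if (!is.null(spec)) return(spec)
    }
    stop("unstable configuration: no stable spec after ", max_tries,
      " attempts",
      call. = FALSE
    )
  })
}

#' The six-variable study-mimic SCM
#'
#' Ground-truth network mirroring the discovered graph for the six daily
#' series (three media-coverage counts, anti- and proregulation tweet
#' counts, background checks): the 13 labelled cross-links with their printed
#' signed partial correlations used as regression weights, plus an AR(1)
#' self-coefficient of 0.4 on every variable so that autocorrelation control
#' is genuinely exercised, and unit innovation variance. With
#' `contaminated = TRUE` the spec additionally carries cosine seasonality at
#' the nine calendar periods and a slow linear trend, emulating the raw
#' (unpreprocessed) series.
#'
#' @param contaminated Add seasonality and trend contamination?
#' @param seasonal_amplitude Cosine amplitude, in innovation SD units, applied
#'   at each period when contaminated.
#' @param trend_slope Linear slope per day when contaminated.
#' @return An `scm_spec` with 6 variables and 13 cross-links.
#' @examples
#' spec <- study_mimic_spec()
#' nrow(tidy(spec))
#' @export
study_mimic_spec <- function(contaminated = FALSE,
                             seasonal_amplitude = 0.5,
                             trend_slope = 1e-3) {
  fx <- load_link_fixture()
  vars <- study_variables()
  links <- tibble::tibble(
    source = match(fx$source, vars),
    sink = match(fx$sink, vars),
    lag = fx$lag,
    coeff = fx$rho
  )
  scm_spec(
    links,
    n_vars = length(vars),
    auto_coeffs = 0.4,
    noise_scales = 1,
    var_names = vars,
    seasonal_amplitudes = if (contaminated) seasonal_amplitude else 0,
    periods = default_periods(),
    trend_slopes = if (contaminated) trend_slope else 0
  )
}

#' Variable codes of the six-variable study panel
#'
#' @return Character vector of the six variable codes, with human-readable
#'   labels as the `labels` attribute.
#' @export
study_variables <- function() {
  structure(
    c(
      "media_laws", "media_shootings", "media_crime",
      "tweets_anti", "tweets_pro", "background_checks"
    ),
    labels = c(
      "Media coverage of firearm laws and regulation",
      "Media coverage of mass shootings",
      "Media coverage of violent crime",
      "Tweets by antiregulation organizations",
      "Tweets by proregulation organizations",
      "Background checks"
    )
  )
}

#' Simulate a daily panel from an SCM
#'
#' Runs the linear recursion
#' \eqn{X_t^j = \sum c\, X_{t-\tau}^i + a_j X_{t-1}^j + s_j(t) + b_j t + \varepsilon_t^j}
#' with independent Gaussian innovations, resolving contemporaneous terms in
#' topological order, discarding a burn-in of `10 * max(lag, 1)` steps, and
#' attaching a daily date index. Deterministic given `(spec, n_days, seed)`.
#'
#' @param spec An `scm_spec`.
#' @param n_days Number of days T to keep (>= max lag + 2).
#' @param seed Integer seed.
#' @param start_date First calendar day of the returned panel.
#' @param overflow Abort if any simulated value exceeds this bound in
#'   magnitude ("divergent simulation").
#' @return A `ts_panel` with `n_days` rows.
#' @export
simulate_panel <- function(spec, n_days, seed,
                           start_date = as.Date("2012-01-01"),
                           overflow = 1e9) {
  stopifnot(inherits(spec, "scm_spec"))
  p <- max(c(1L, spec$links$lag))
  if (n_days < p + 2) stop("n_days must be at least lag_max + 2", call. = FALSE)
  burn <- 10L * max(p, 1L)
  total <- n_days + burn
  n <- spec$n_vars
  topo <- topo_order_lag0(spec)
  lagged <- dplyr::filter(spec$links, .data$lag > 0L)
  l0 <- dplyr::filter(spec$links, .data$lag == 0L)
  # per-sink plain vectors: tibble subsetting inside the time loop is too slow
  lsrc <- lapply(seq_len(n), function(j) lagged$source[lagged$sink == j])
  llag <- lapply(seq_len(n), function(j) lagged$lag[lagged$sink == j])
  lcoef <- lapply(seq_len(n), function(j) lagged$coeff[lagged$sink == j])
  csrc <- lapply(seq_len(n), function(j) l0$source[l0$sink == j])
  ccoef <- lapply(seq_len(n), function(j) l0$coeff[l0$sink == j])
  auto <- spec$auto_coeffs
  X <- withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(total * n), total, n) %*% diag(spec$noise_scales, n)
    X <- matrix(0, total, n)
    tt <- seq_len(total) - burn # calendar time; burn-in sits at t <= 0
    det_term <- matrix(0, total, n)
    for (j in seq_len(n)) {
      amp <- spec$seasonal_amplitudes[j, ]
      if (any(amp > 0)) {
        for (k in seq_along(spec$periods)) {
          if (amp[k] > 0) {
            det_term[, j] <- det_term[, j] +
              amp[k] * cos(2 * pi * tt / spec$periods[k])
          }
        }
      }
      if (spec$trend_slopes[j] != 0) {
        det_term[, j] <- det_term[, j] + spec$trend_slopes[j] * tt
      }
    }
    for (t in seq_len(total)) {
      for (j in topo) {
        v <- eps[t, j] + det_term[t, j]
        if (t > 1) v <- v + auto[j] * X[t - 1, j]
        if (length(lsrc[[j]]) > 0) {
          ok <- t - llag[[j]] >= 1
          if (any(ok)) {
            v <- v + sum(lcoef[[j]][ok] *
              X[cbind(t - llag[[j]][ok], lsrc[[j]][ok])])
          }
        }
        if (length(csrc[[j]]) > 0) {
          v <- v + sum(ccoef[[j]] * X[t, csrc[[j]]])
        }
        X[t, j] <- v
      }
    }
    X
  })
  if (any(!is.finite(X)) || max(abs(X)) > overflow) {
    stop("divergent simulation: values exceeded the overflow bound", call. = FALSE)
  }
  keep <- X[burn + seq_len(n_days), , drop = FALSE]
  colnames(keep) <- spec$var_names
  out <- dplyr::bind_cols(
    tibble::tibble(date = seq(start_date, by = "day", length.out = n_days)),
    tibble::as_tibble(keep)
  )
  as_ts_panel(out)
}

#' Ground-truth causal graph of an SCM
#'
#' One directed link per nonzero cross-coefficient; AR(1) self-dependencies
#' are excluded from the cross-link set and recorded in the `auto` attribute.
#'
#' @param spec An `scm_spec`.
#' @return A `causal_graph` whose `rho` column carries the planted
#'   coefficients and whose p-values are `NA` (truth, not inference).
#' @export
true_graph <- function(spec) {
  cl <- cross_links(spec)
  links <- tibble::tibble(
    source = spec$var_names[cl$source],
    sink = spec$var_names[cl$sink],
    lag = cl$lag,
    rho = cl$coeff,
    p_value = NA_real_,
    orientation = "directed"
  )
  new_causal_graph(
    links = links,
    var_names = spec$var_names,
    tau_max = max(c(1L, cl$lag)),
    alpha = NA_real_,
    n_eff = NA_integer_,
    auto = spec$auto_coeffs
  )
}

#' @importFrom generics tidy
#' @method tidy scm_spec
#' @export
tidy.scm_spec <- function(x, ...) {
  dplyr::mutate(
    x$links,
    source = x$var_names[.data$source],
    sink = x$var_names[.data$sink]
  )
}

#' @importFrom generics glance
#' @method glance scm_spec
#' @export
glance.scm_spec <- function(x, ...) {
  tibble::tibble(
    n_vars = x$n_vars,
    n_cross_links = nrow(cross_links(x)),
    lag_max = max(c(0L, x$links$lag)),
    spectral_radius = spectral_radius(x)
  )
}

#' Read and write SCM specs as JSON
#'
#' The schema is a flat object with variable names, per-variable AR(1) and
#' noise parameters, and a `links` array of `{source, sink, lag, coeff}`
#' records (names, not indices).
#'
#' @param spec An `scm_spec`.
#' @param path File path.
#' @return `read_scm_json()` returns an `scm_spec`.
#' @export
write_scm_json <- function(spec, path) {
  obj <- list(
    var_names = spec$var_names,
    auto_coeffs = spec$auto_coeffs,
    noise_scales = spec$noise_scales,
    periods = spec$periods,
    seasonal_amplitudes = spec$seasonal_amplitudes,
    trend_slopes = spec$trend_slopes,
    links = dplyr::mutate(
      spec$links,
      source = spec$var_names[.data$source],
      sink = spec$var_names[.data$sink]
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(spec)
}

#' @rdname write_scm_json
#' @export
read_scm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  links <- tibble::as_tibble(obj$links)
  scm_spec(
    dplyr::mutate(
      links,
      source = match(.data$source, obj$var_names),
      sink = match(.data$sink, obj$var_names)
    ),
    n_vars = length(obj$var_names),
    auto_coeffs = obj$auto_coeffs,
    noise_scales = obj$noise_scales,
    var_names = obj$var_names,
    seasonal_amplitudes = matrix(obj$seasonal_amplitudes,
      nrow = length(obj$var_names)
    ),
    periods = obj$periods,
    trend_slopes = obj$trend_slopes
  )
}
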