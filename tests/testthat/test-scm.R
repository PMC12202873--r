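test_that("density-zero random SCM has no cross-links and is reproducible", {
  spec <- make_random_scm(3, cross_density = 0, lag_max = 2, seed = 1)
  expect_s3_class(spec, "scm_spec")
  expect_equal(nrow(tidy(spec)), 0)
  s1 <- make_random_scm(4, cross_density = 0.15, lag_max = 3, seed = 7)
  s2 <- make_random_scm(4, cross_density = 0.15, lag_max = 3, seed = 7)
  expect_identical(s1$links, s2$links)
  expect_identical(s1$auto_coeffs, s2$auto_coeffs)
})

test_that("every emitted SCM is stable by an independent eigenvalue check", {
  # oracle: rebuild the companion matrix from the raw link list, reducing
  # the contemporaneous part by (I - B0)^{-1}, independent of the package's
  # own builder
  companion_radius <- function(spec) {
    n <- spec$n_vars
    p <- max(c(1L, spec$links$lag))
    B0 <- matrix(0, n, n)
    A <- array(0, c(n, n, p))
    for (r in seq_len(nrow(spec$links))) {
      src <- spec$links$source[r]
      snk <- spec$links$sink[r]
      lg <- spec$links$lag[r]
      cf <- spec$links$coeff[r]
      if (lg == 0) B0[snk, src] <- B0[snk, src] + cf else A[snk, src, lg] <- A[snk, src, lg] + cf
    }
    for (j in seq_len(n)) A[j, j, 1] <- A[j, j, 1] + spec$auto_coeffs[j]
    top <- do.call(cbind, lapply(seq_len(p), function(l) {
      solve(diag(n) - B0) %*% A[, , l]
    }))
    comp <- rbind(top, cbind(diag(n * (p - 1)), matrix(0, n * (p - 1), n)))
    if (p == 1) comp <- top
    max(Mod(eigen(comp, only.values = TRUE)$values))
  }
  for (seed in 1:20) {
    spec <- make_random_scm(4,
      cross_density = 0.2, lag_max = 3, seed = seed,
      coeff_range = c(0.2, 0.6), auto_coeffs = 0.5
    )
    r <- companion_radius(spec)
    expect_lt(r, 1)
    expect_equal(spectral_radius(spec), r, tolerance = 1e-10)
  }
  # a plainly explosive system is rejected
  expect_error(
    scm_spec(
      tibble::tibble(source = 1L, sink = 2L, lag = 1L, coeff = 0.5),
      n_vars = 2, auto_coeffs = 1.05
    ),
    "unstable"
  )
})

test_that("contemporaneous cycles and lag-0 self-links are rejected", {
  expect_error(
    scm_spec(
      tibble::tibble(
        source = c(1L, 2L), sink = c(2L, 1L),
        lag = c(0L, 0L), coeff = c(0.3, 0.3)
      ),
      n_vars = 2
    ),
    "acyclic"
  )
  expect_error(
    scm_spec(
      tibble::tibble(source = 1L, sink = 1L, lag = 0L, coeff = 0.3),
      n_vars = 2
    ),
    "self-link"
  )
})

test_that("degenerate noiseless spec simulates to an all-zero panel", {
  spec <- scm_spec(
    tibble::tibble(source = integer(), sink = integer(), lag = integer(), coeff = numeric()),
    n_vars = 3, auto_coeffs = 0, noise_scales = 0
  )
  p <- simulate_panel(spec, 100, seed = 1)
  expect_true(all(as.matrix(p[-1]) == 0))
})

test_that("AR(1) simulation reproduces the closed-form lag-1 autocorrelation", {
  spec <- scm_spec(
    tibble::tibble(source = integer(), sink = integer(), lag = integer(), coeff = numeric()),
    n_vars = 1, auto_coeffs = 0.5, noise_scales = 1
  )
  p <- simulate_panel(spec, 50000, seed = 11)
  x <- p[[2]]
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 0.02)
})

test_that("simulation is bit-identical under a repeated seed and leaves the RNG alone", {
  spec <- make_random_scm(3, cross_density = 0.2, lag_max = 2, seed = 5)
  set.seed(99)
  before <- .Random.seed
  p1 <- simulate_panel(spec, 200, seed = 8)
  expect_identical(before, .Random.seed)
  p2 <- simulate_panel(spec, 200, seed = 8)
  expect_identical(p1, p2)
})

test_that("pure-noise simulation matches the nominal moments within 3 SE", {
  spec <- scm_spec(
    tibble::tibble(source = integer(), sink = integer(), lag = integer(), coeff = numeric()),
    n_vars = 2, auto_coeffs = 0, noise_scales = c(1, 2)
  )
  p <- simulate_panel(spec, 10000, seed = 21)
  n <- 10000
  for (j in 1:2) {
    sd_j <- c(1, 2)[j]
    x <- p[[j + 1]]
    expect_lt(abs(mean(x)), 3 * sd_j / sqrt(n))
    # SE of the sample variance of a normal: sigma^2 * sqrt(2/(n-1))
    expect_lt(abs(var(x) - sd_j^2), 3 * sd_j^2 * sqrt(2 / (n - 1)))
  }
})

test_that("the study-mimic spec carries the reference network", {
  spec <- study_mimic_spec()
  links <- tidy(spec)
  expect_equal(nrow(links), 13)
  expect_equal(spec$auto_coeffs, rep(0.4, 6))
  k <- dplyr::filter(
    links,
    source == "media_laws", sink == "background_checks", lag == 1
  )
  expect_equal(k$coeff, 0.084)
  l0 <- dplyr::filter(links, lag == 0)
  expect_setequal(l0$source, c("media_laws", "media_crime"))
  tg <- true_graph(spec)
  expect_equal(nrow(tg$links), 13)
})

test_that("true_graph of a density-zero spec is empty and graphs round-trip JSON", {
  spec <- make_random_scm(3, cross_density = 0, lag_max = 2, seed = 2)
  expect_equal(nrow(true_graph(spec)$links), 0)
  g <- true_graph(study_mimic_spec())
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_equal(g2$links, g$links)
  expect_equal(g2$var_names, g$var_names)
})

test_that("SCM specs round-trip through JSON", {
  spec <- study_mimic_spec(contaminated = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_scm_json(spec, path)
  spec2 <- read_scm_json(path)
  expect_equal(spec2$links, spec$links)
  expect_equal(spec2$seasonal_amplitudes, spec$seasonal_amplitudes)
  expect_equal(spec2$trend_slopes, spec$trend_slopes)
  expect_identical(
    simulate_panel(spec, 120, seed = 4),
    simulate_panel(spec2, 120, seed = 4)
  )
})
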