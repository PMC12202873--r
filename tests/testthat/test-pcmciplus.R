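test_that("false cross-adjacencies on independent noise obey the binomial bound", {
  n_seeds <- 100
  alpha <- 0.01
  false_total <- 0
  n_candidates <- 0
  for (seed in seq_len(n_seeds)) {
    p <- white_noise_panel(1000, 3, seed = 4000 + seed)
    sk <- discover_skeleton(p, tau_max = 2, alpha = alpha)
    adj <- dplyr::bind_rows(lapply(seq_along(sk$adj), function(j) {
      g <- sk$adj[[j]]
      g$sink <- rep(j, nrow(g))
      g
    }))
    # cross-adjacencies only: self lag-links are genuine AR candidates
    false_total <- false_total + sum(adj$i != adj$sink)
    n_candidates <- n_candidates + 3 * (3 * 3 - 1) # per sink: 3*(tau+1)-1, minus self rows
  }
  # per spec'd bound: expected false adjacency count <= 2 * alpha * candidates
  expect_lte(false_total / n_seeds, 2 * alpha * (3 * (3 * 3 - 1)))
})

test_that("a planted lagged link is recovered almost always", {
  spec <- planted_pair_spec(c = 0.5, lag = 1)
  hits <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    p <- simulate_panel(spec, 2000, seed = 100 + seed)
    g <- run_pcmciplus(p, tau_max = 2, alpha = 0.05)
    ok <- any(g$links$source == "X" & g$links$sink == "Y" & g$links$lag == 1)
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("conditioning removes the spurious lag-2 shortcut of a lagged chain", {
  # X_{t-1} -> Y_t, Y_{t-1} -> Z_t: the marginal X->Z lag-2 association must
  # vanish once Y is conditioned on
  spec <- scm_spec(
    tibble::tibble(
      source = c(1L, 2L), sink = c(2L, 3L),
      lag = c(1L, 1L), coeff = c(0.6, 0.6)
    ),
    n_vars = 3, auto_coeffs = 0.2, var_names = c("X", "Y", "Z")
  )
  removed <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    p <- simulate_panel(spec, 2000, seed = 200 + seed)
    g <- run_pcmciplus(p, tau_max = 3, alpha = 0.05)
    shortcut <- any(
      g$links$source == "X" & g$links$sink == "Z" & g$links$lag == 2
    )
    if (!shortcut) removed <- removed + 1
  }
  expect_gte(removed / n_seeds, 0.90)
})

test_that("contemporaneous colliders are oriented into the collider node", {
  # X -> Z <- Y at lag 0 with X and Y independent
  spec <- scm_spec(
    tibble::tibble(
      source = c(1L, 2L), sink = c(3L, 3L),
      lag = c(0L, 0L), coeff = c(0.5, 0.5)
    ),
    n_vars = 3, auto_coeffs = 0.3, var_names = c("X", "Y", "Z")
  )
  oriented <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    p <- simulate_panel(spec, 2000, seed = 300 + seed)
    g <- run_pcmciplus(p, tau_max = 2, alpha = 0.05)
    l0 <- g$links[g$links$lag == 0 & g$links$orientation == "directed", ]
    both_in <- sum(l0$sink == "Z" & l0$source %in% c("X", "Y")) == 2
    if (both_in) oriented <- oriented + 1
  }
  expect_gte(oriented / n_seeds, 0.90)
})

test_that("a lone contemporaneous dependence stays unoriented", {
  spec <- scm_spec(
    tibble::tibble(source = 1L, sink = 2L, lag = 0L, coeff = 0.5),
    n_vars = 2, auto_coeffs = 0.3, var_names = c("X", "Y")
  )
  p <- simulate_panel(spec, 2000, seed = 77)
  g <- run_pcmciplus(p, tau_max = 2, alpha = 0.05)
  l0 <- g$links[g$links$lag == 0, ]
  expect_equal(nrow(l0), 1)
  expect_equal(l0$orientation, "unoriented")
})

test_that("structural invariants hold: no lag-0 self-links, lagged links directed", {
  spec <- study_mimic_spec()
  p <- simulate_panel(spec, 800, seed = 55)
  g <- run_pcmciplus(p, tau_max = 4, alpha = 0.05)
  expect_false(any(g$links$lag == 0 & g$links$source == g$links$sink))
  lagged <- g$links[g$links$lag >= 1, ]
  expect_true(all(lagged$orientation == "directed"))
  expect_true(all(g$links$orientation %in% c("directed", "unoriented", "conflict")))
})

test_that("the engine is deterministic and alpha-monotone at the MCI stage", {
  spec <- study_mimic_spec()
  p <- simulate_panel(spec, 1200, seed = 66)
  g1 <- run_pcmciplus(p, tau_max = 3, alpha = 0.05)
  g2 <- run_pcmciplus(p, tau_max = 3, alpha = 0.05)
  expect_identical(g1$links, g2$links)
  # the stricter-alpha MCI retention is a subset within the same skeleton
  sk <- discover_skeleton(p, tau_max = 3, alpha = 0.05)
  oriented <- orient_links(sk)
  loose <- mci_validate(p, oriented, alpha = 0.05)
  strict <- mci_validate(p, oriented, alpha = 0.001)
  key <- function(g) paste(g$links$source, g$links$sink, g$links$lag)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("with empty parent sets the MCI p-value reduces to the plain pair test", {
  p <- white_noise_panel(500, 2, seed = 91)
  tau_max <- 2
  graph <- causalpanel:::new_causal_graph(
    links = tibble::tibble(
      source = "V1", sink = "V2", lag = 1L,
      rho = NA_real_, p_value = NA_real_, orientation = "directed"
    ),
    var_names = c("V1", "V2"), tau_max = tau_max, alpha = 0.05,
    n_eff = NA_integer_,
    parents = list(
      V1 = tibble::tibble(parent = character(), lag = integer()),
      V2 = tibble::tibble(parent = character(), lag = integer())
    )
  )
  res <- mci_validate(p, graph, alpha = 1)
  rows <- (2 * tau_max + 1):nrow(p)
  plain <- parcorr_test(p$V1[rows - 1], p$V2[rows])
  expect_equal(res$links$p_value, plain$p_value, tolerance = 1e-12)
  expect_equal(res$links$rho, plain$rho, tolerance = 1e-12)
})

test_that("MCI conditioning controls autocorrelation-inflated false links", {
  # X strongly autocorrelated, Y independent white noise: without parent
  # conditioning the lagged X -> Y tests are anticonservative
  spec <- scm_spec(
    tibble::tibble(source = integer(), sink = integer(), lag = integer(), coeff = numeric()),
    n_vars = 2, auto_coeffs = c(0.9, 0), var_names = c("X", "Y")
  )
  false_hits <- 0
  n_seeds <- 200
  for (seed in seq_len(n_seeds)) {
    p <- simulate_panel(spec, 1000, seed = 500 + seed)
    g <- run_pcmciplus(p, tau_max = 3, alpha = 0.05)
    if (any(g$links$source == "X" & g$links$sink == "Y")) {
      false_hits <- false_hits + 1
    }
  }
  expect_lte(false_hits / n_seeds, 0.10)
})

test_that("recovery scoring matches by identity with unordered lag-0 pairs", {
  truth <- true_graph(study_mimic_spec())
  # a fake discovered graph: one correct lagged link, one lag-0 link stored
  # in the flipped direction, one false alarm
  fake <- causalpanel:::new_causal_graph(
    links = tibble::tibble(
      source = c("media_shootings", "media_crime", "tweets_pro"),
      sink = c("media_laws", "media_laws", "media_shootings"),
      lag = c(1L, 0L, 3L),
      rho = c(0.09, -0.1, 0.05),
      p_value = c(0.001, 0.001, 0.01),
      orientation = c("directed", "unoriented", "directed")
    ),
    var_names = truth$var_names, tau_max = 7, alpha = 0.05, n_eff = 2900
  )
  sc <- score_graph_recovery(fake, truth)
  expect_equal(sum(sc$detected), 2)
  expect_equal(attr(sc, "n_false_alarms"), 1)
  b <- sc[sc$source == "media_laws" & sc$sink == "media_crime", ]
  expect_true(b$detected) # matched despite flipped storage order
  expect_false(b$sign_ok) # and the sign mismatch is flagged
})
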