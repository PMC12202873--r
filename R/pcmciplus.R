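# Build the aligned lagged design for one discovery run.
#
# Every conditional-independence test in a run (skeleton and MCI stages)
# uses the single row set t = 2*tau_max + 1, ..., T, because the MCI stage
# conditions on time-shifted parents of the source whose lags reach
# 2*tau_max; a single aligned sample avoids sample-size drift across tests.
# Column (i, lag) of the design holds X^i_{t - lag}.
.build_lagged <- function(panel, tau_max) {
  validate_ts_panel(panel)
  X <- panel_matrix(panel)
  n_vars <- ncol(X)
  T_len <- nrow(X)
  max_shift <- 2L * tau_max
  if (T_len <= (tau_max + 2) * n_vars || T_len <= max_shift + 3) {
    stop("sample too short for tau_max", call. = FALSE)
  }
  rows <- (max_shift + 1):T_len
  L <- matrix(0, length(rows), n_vars * (max_shift + 1))
  for (lag in 0:max_shift) {
    L[, lag * n_vars + seq_len(n_vars)] <- X[rows - lag, , drop = FALSE]
  }
  list(
    L = L, n_eff = length(rows), n_vars = n_vars,
    tau_max = tau_max, max_shift = max_shift,
    var_names = colnames(X)
  )
}

.cidx <- function(i, lag, n_vars) lag * n_vars + i

# order candidate parents by descending |rho|, ties by (variable, lag)
.order_parents <- function(df) {
  df[order(-abs(df$rho), df$i, df$lag), , drop = FALSE]
}

.pair_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

# Two-phase PC-stable condition-selection skeleton on a prebuilt design.
#
# Phase 1 (lagged condition-selection): candidates (i, tau >= 1) -> j are
# pruned level by level, each link tested given the s strongest current
# *lagged* parents of its sink. Phase 2 (contemporaneous PC): lag-0 pairs
# are tested given the s strongest current lag-0 neighbours of the sink
# together with the phase-1 lagged parents of both endpoints. Keeping lag-0
# neighbours out of the lagged conditioning sets matters: a contemporaneous
# neighbour can be a *child* of the sink, and conditioning on a common
# child induces explaining-away that attenuates true lagged links. Spurious
# lagged links that only a contemporaneous conditioner could remove are
# caught later by the MCI stage, which conditions on the full adjacency.
.skeleton <- function(lag_data, alpha) {
  L <- lag_data$L
  N <- lag_data$n_vars
  tau_max <- lag_data$tau_max
  n_eff <- lag_data$n_eff
  n_tests <- 0L
  run_test <- function(i, lg, j, Z) {
    Z <- Z[!(Z$i == i & Z$lag == lg) & !(Z$i == j & Z$lag == 0L), ,
      drop = FALSE
    ]
    Z <- unique(Z)
    if (n_eff - nrow(Z) - 2 < 1) {
      stop("sample too short for tau_max", call. = FALSE)
    }
    n_tests <<- n_tests + 1L
    list(
      res = .parcorr(
        L[, c(.cidx(i, lg, N), .cidx(j, 0L, N))],
        L[, .cidx(Z$i, Z$lag, N), drop = FALSE]
      ),
      Z = Z
    )
  }
  # phase 1: lagged links only
  cand <- lapply(seq_len(N), function(j) {
    g <- expand.grid(i = seq_len(N), lag = seq_len(tau_max))
    g$rho <- Inf # untested links rank first and are never pruned untested
    g$p <- NA_real_
    g$alive <- TRUE
    g
  })
  s <- 0L
  repeat {
    frozen <- lapply(cand, function(g) g[g$alive, , drop = FALSE])
    tested_any <- FALSE
    removals <- vector("list", N)
    for (j in seq_len(N)) {
      gj <- frozen[[j]]
      if (nrow(gj) == 0) next
      for (r in seq_len(nrow(gj))) {
        others <- .order_parents(gj[-r, , drop = FALSE])
        if (nrow(others) < s) next # no conditioning set of size s
        tested_any <- TRUE
        tst <- run_test(
          gj$i[r], gj$lag[r], j,
          others[seq_len(s), c("i", "lag"), drop = FALSE]
        )
        ri <- which(cand[[j]]$i == gj$i[r] & cand[[j]]$lag == gj$lag[r])
        cand[[j]]$rho[ri] <- tst$res[1]
        cand[[j]]$p[ri] <- tst$res[2]
        if (tst$res[2] > alpha) removals[[j]] <- c(removals[[j]], ri)
      }
    }
    for (j in seq_len(N)) cand[[j]]$alive[removals[[j]]] <- FALSE
    if (!tested_any) break
    s <- s + 1L
  }
  lagged_parents <- lapply(cand, function(g) {
    g[g$alive, c("i", "lag"), drop = FALSE]
  })
  # phase 2: contemporaneous pairs, conditioned on discovered lagged parents
  # of both endpoints plus growing subsets of lag-0 neighbours
  cand0 <- lapply(seq_len(N), function(j) {
    g <- expand.grid(i = setdiff(seq_len(N), j), lag = 0L)
    g$rho <- Inf
    g$p <- NA_real_
    g$alive <- TRUE
    g
  })
  sepsets <- list()
  s <- 0L
  repeat {
    frozen <- lapply(cand0, function(g) g[g$alive, , drop = FALSE])
    tested_any <- FALSE
    removals <- vector("list", N)
    for (j in seq_len(N)) {
      gj <- frozen[[j]]
      if (nrow(gj) == 0) next
      for (r in seq_len(nrow(gj))) {
        i <- gj$i[r]
        others <- .order_parents(gj[-r, , drop = FALSE])
        if (nrow(others) < s) next
        tested_any <- TRUE
        Z <- rbind(
          others[seq_len(s), c("i", "lag"), drop = FALSE],
          lagged_parents[[j]], lagged_parents[[i]]
        )
        tst <- run_test(i, 0L, j, Z)
        ri <- which(cand0[[j]]$i == i)
        cand0[[j]]$rho[ri] <- tst$res[1]
        cand0[[j]]$p[ri] <- tst$res[2]
        if (tst$res[2] > alpha) {
          removals[[j]] <- c(removals[[j]], ri)
          sepsets[[.pair_key(i, j)]] <- tst$Z
        }
      }
    }
    for (j in seq_len(N)) {
      if (length(removals[[j]]) > 0) {
        cand0[[j]]$alive[removals[[j]]] <- FALSE
        # lag-0 adjacency is symmetric: removing i--j removes the mirror
        for (i in cand0[[j]]$i[removals[[j]]]) {
          cand0[[i]]$alive[cand0[[i]]$i == j] <- FALSE
        }
      }
    }
    if (!tested_any) break
    s <- s + 1L
  }
  adj <- lapply(seq_len(N), function(j) {
    g <- cand[[j]]
    g0 <- cand0[[j]]
    out <- rbind(
      g0[g0$alive, c("i", "lag", "rho", "p"), drop = FALSE],
      g[g$alive, c("i", "lag", "rho", "p"), drop = FALSE]
    )
    rownames(out) <- NULL
    out
  })
  structure(
    list(
      adj = adj, sepsets = sepsets, var_names = lag_data$var_names,
      n_vars = N, tau_max = tau_max, alpha = alpha, n_eff = n_eff,
      n_tests = n_tests
    ),
    class = "pcmci_skeleton"
  )
}

#' Discover the causal skeleton of a panel
#'
#' PC-stable condition-selection over all candidate links
#' \eqn{X^i_{t-\tau} \to X^j_t}, \eqn{\tau = 0..\tau_{max}} (lag-0 self-links
#' excluded), in the algorithm's two phases. First the lagged candidates are
#' pruned: at conditioning-set size s = 0, 1, 2, ... each remaining lagged
#' link is tested given the s strongest current lagged parents of its sink
#' (strength = |rho| from the previous level). Then contemporaneous pairs
#' are tested given the s strongest current lag-0 neighbours of the sink,
#' additionally conditioned on the discovered lagged parents of both
#' endpoints. Adjacencies are frozen within each level (stable variant),
#' links with p > alpha are removed at level end, and separating sets are
#' recorded for collider orientation.
#'
#' @param panel A (preprocessed) `ts_panel`; a warning is issued if any
#'   variable fails the stationarity gate.
#' @param tau_max Largest lag tested (>= 1).
#' @param alpha Significance level for link removal.
#' @param check_stationarity Run the ADF/KPSS gate and warn on failures?
#' @return A `pcmci_skeleton`: adjacency sets with test records, separating
#'   sets, and run metadata.
#' @export
discover_skeleton <- function(panel, tau_max = 7, alpha = 0.05,
                              check_stationarity = FALSE) {
  stopifnot(tau_max >= 1, alpha > 0, alpha < 1)
  if (check_stationarity) {
    rep <- stationarity_report(panel)
    if (!all(rep$stationary)) {
      warning(
        "variables failing the stationarity gate: ",
        paste(rep$variable[!rep$stationary], collapse = ", "),
        call. = FALSE
      )
    }
  }
  .skeleton(.build_lagged(panel, as.integer(tau_max)), alpha)
}

#' @export
print.pcmci_skeleton <- function(x, ...) {
  n_links <- sum(vapply(x$adj, nrow, integer(1)))
  cat("PCMCI+ skeleton: ", x$n_vars, " variables, tau_max ", x$tau_max,
    ", alpha ", x$alpha, "; ", n_links,
    " surviving directed candidates after ", x$n_tests, " CI tests\n",
    sep = ""
  )
  invisible(x)
}

new_causal_graph <- function(links, var_names, tau_max, alpha, n_eff,
                             parents = NULL, auto = NULL) {
  structure(
    list(
      links = links, var_names = var_names, n_vars = length(var_names),
      tau_max = tau_max, alpha = alpha, n_eff = n_eff,
      parents = parents, auto = auto
    ),
    class = "causal_graph"
  )
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("Causal graph: ", x$n_vars, " variables, ", nrow(x$links), " links (",
    sum(x$links$lag == 0), " contemporaneous), tau_max ", x$tau_max, "\n",
    sep = ""
  )
  print(x$links, ...)
  invisible(x)
}

#' Orient the links of a discovered skeleton
#'
#' Lagged links are oriented past-to-present by time order. Contemporaneous
#' links are oriented by the collider rule -- for any unshielded triple
#' i -- k -- j whose middle node k is absent from the separating set of
#' (i, j), orient i -> k <- j -- followed by the standard propagation
#' (Meek) rules. Links reached by no rule stay `"unoriented"`; links where
#' rules disagree are marked `"conflict"`.
#'
#' @param skeleton A `pcmci_skeleton` from [discover_skeleton()].
#' @return A `causal_graph` whose parent map is the skeleton adjacency
#'   (needed by [mci_validate()]).
#' @export
orient_links <- function(skeleton) {
  stopifnot(inherits(skeleton, "pcmci_skeleton"))
  N <- skeleton$n_vars
  vn <- skeleton$var_names
  lagged_rows <- list()
  for (j in seq_len(N)) {
    g <- skeleton$adj[[j]]
    g <- g[g$lag >= 1L, , drop = FALSE]
    if (nrow(g) > 0) {
      lagged_rows[[length(lagged_rows) + 1]] <- tibble::tibble(
        source = vn[g$i], sink = vn[j], lag = g$lag,
        rho = g$rho, p_value = g$p, orientation = "directed"
      )
    }
  }
  # contemporaneous adjacency, one record per unordered pair
  amat <- matrix(0L, N, N) # 0 none, 1 i--j, 2 i->j, 3 j->i, 4 conflict
  pair_stat <- list()
  for (j in seq_len(N)) {
    g <- skeleton$adj[[j]]
    g <- g[g$lag == 0L, , drop = FALSE]
    for (r in seq_len(nrow(g))) {
      i <- g$i[r]
      if (amat[i, j] == 0L && amat[j, i] == 0L) {
        amat[i, j] <- amat[j, i] <- 1L
      }
      k <- .pair_key(i, j)
      if (is.null(pair_stat[[k]]) || g$p[r] < pair_stat[[k]][2]) {
        pair_stat[[k]] <- c(g$rho[r], g$p[r])
      }
    }
  }
  adjacent0 <- function(i, j) amat[i, j] != 0L
  orient_edge <- function(from, to) {
    # returns FALSE on conflict with an existing opposite orientation
    if (amat[from, to] == 2L) return(TRUE)
    if (amat[from, to] == 3L || amat[to, from] == 2L) {
      amat[from, to] <<- amat[to, from] <<- 4L
      return(FALSE)
    }
    if (amat[from, to] == 4L) return(FALSE)
    amat[from, to] <<- 2L
    amat[to, from] <<- 3L
    TRUE
  }
  # collider rule on unshielded triples
  for (k in seq_len(N)) {
    nb <- which(vapply(seq_len(N), function(i) i != k && adjacent0(i, k), logical(1)))
    if (length(nb) < 2) next
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a >= b) next
        i <- nb[a]
        j <- nb[b]
        if (adjacent0(i, j)) next
        ss <- skeleton$sepsets[[.pair_key(i, j)]]
        in_sepset <- !is.null(ss) && any(ss$i == k & ss$lag == 0L)
        if (!in_sepset) {
          orient_edge(i, k)
          orient_edge(j, k)
        }
      }
    }
  }
  # Meek propagation rules, to fixpoint
  repeat {
    changed <- FALSE
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (i == j || amat[i, j] != 1L) next
        # R1: k -> i, i -- j, k and j nonadjacent => i -> j
        for (k in seq_len(N)) {
          if (amat[k, i] == 2L && !adjacent0(k, j) && k != j) {
            if (orient_edge(i, j)) changed <- TRUE
            break
          }
        }
        if (amat[i, j] != 1L) next
        # R2: i -> k -> j and i -- j => i -> j
        for (k in seq_len(N)) {
          if (k != i && k != j && amat[i, k] == 2L && amat[k, j] == 2L) {
            if (orient_edge(i, j)) changed <- TRUE
            break
          }
        }
        if (amat[i, j] != 1L) next
        # R3: i -- k, i -- l, k -> j, l -> j, k/l nonadjacent, i -- j => i -> j
        nbs <- which(vapply(
          seq_len(N),
          function(k) k != i && k != j && amat[i, k] == 1L && amat[k, j] == 2L,
          logical(1)
        ))
        if (length(nbs) >= 2) {
          pairs <- utils::combn(nbs, 2)
          for (cix in seq_len(ncol(pairs))) {
            if (!adjacent0(pairs[1, cix], pairs[2, cix])) {
              if (orient_edge(i, j)) changed <- TRUE
              break
            }
          }
        }
      }
    }
    if (!changed) break
  }
  contemp_rows <- list()
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i >= j || amat[i, j] == 0L) next
      st <- pair_stat[[.pair_key(i, j)]]
      row <- switch(as.character(amat[i, j]),
        "1" = tibble::tibble(
          source = vn[i], sink = vn[j], orientation = "unoriented"
        ),
        "2" = tibble::tibble(
          source = vn[i], sink = vn[j], orientation = "directed"
        ),
        "3" = tibble::tibble(
          source = vn[j], sink = vn[i], orientation = "directed"
        ),
        "4" = tibble::tibble(
          source = vn[i], sink = vn[j], orientation = "conflict"
        )
      )
      row$lag <- 0L
      row$rho <- st[1]
      row$p_value <- st[2]
      contemp_rows[[length(contemp_rows) + 1]] <- row
    }
  }
  links <- dplyr::bind_rows(c(lagged_rows, contemp_rows))
  if (nrow(links) == 0) {
    links <- tibble::tibble(
      source = character(), sink = character(), lag = integer(),
      rho = numeric(), p_value = numeric(), orientation = character()
    )
  }
  links <- links[, c("source", "sink", "lag", "rho", "p_value", "orientation")]
  # Parent map for the MCI stage: the lagged adjacency plus contemporaneous
  # links oriented *into* the variable. Unoriented lag-0 neighbours are kept
  # as candidate links but never as conditioners: an unoriented neighbour
  # may be a child of the variable, and conditioning on a common child
  # biases true lagged effects towards zero by explaining-away.
  parents <- lapply(seq_len(N), function(j) {
    g <- skeleton$adj[[j]]
    g <- g[g$lag >= 1L, , drop = FALSE]
    in0 <- which(vapply(seq_len(N), function(i) amat[i, j] == 2L, logical(1)))
    tibble::tibble(
      parent = c(vn[g$i], vn[in0]),
      lag = c(g$lag, rep(0L, length(in0)))
    )
  })
  names(parents) <- vn
  new_causal_graph(
    links = dplyr::arrange(links, .data$sink, .data$lag, .data$source),
    var_names = vn, tau_max = skeleton$tau_max,
    alpha = skeleton$alpha, n_eff = skeleton$n_eff, parents = parents
  )
}

#' Momentary-conditional-independence validation
#'
#' The final stage: every skeleton link \eqn{X^i_{t-\tau} \to X^j_t} is
#' retested conditioning on the skeleton parents of the sink (minus the
#' candidate) together with the lagged parents of the source, time-shifted
#' by \eqn{\tau}. Conditioning on both parent sets controls the inflation of
#' dependence that autocorrelation induces. Links with MCI p-value
#' \eqn{\le \alpha} are retained, carrying their MCI `rho` and `p_value`.
#'
#' @param panel The same panel the skeleton was discovered on.
#' @param graph A `causal_graph` from [orient_links()] carrying the skeleton
#'   parent map.
#' @param alpha Significance level for retention.
#' @return A `causal_graph` of validated links; the parent map is updated to
#'   the validated links.
#' @export
mci_validate <- function(panel, graph, alpha = graph$alpha) {
  stopifnot(inherits(graph, "causal_graph"), !is.null(graph$parents))
  lag_data <- .build_lagged(panel, graph$tau_max)
  stopifnot(identical(lag_data$var_names, graph$var_names))
  N <- lag_data$n_vars
  vn <- graph$var_names
  links <- graph$links
  keep <- logical(nrow(links))
  rho <- p <- numeric(nrow(links))
  for (r in seq_len(nrow(links))) {
    i <- match(links$source[r], vn)
    j <- match(links$sink[r], vn)
    lg <- links$lag[r]
    pj <- graph$parents[[vn[j]]]
    pj_idx <- tibble::tibble(i = match(pj$parent, vn), lag = pj$lag)
    pj_idx <- pj_idx[!(pj_idx$i == i & pj_idx$lag == lg), , drop = FALSE]
    pi <- graph$parents[[vn[i]]]
    pi_idx <- tibble::tibble(i = match(pi$parent, vn), lag = pi$lag)
    pi_idx <- pi_idx[pi_idx$lag >= 1L, , drop = FALSE]
    pi_idx$lag <- pi_idx$lag + lg # time-shift the source's parents
    Z <- unique(rbind(pj_idx, pi_idx))
    Z <- Z[!(Z$i == j & Z$lag == 0L) & !(Z$i == i & Z$lag == lg), ,
      drop = FALSE
    ]
    if (lag_data$n_eff - nrow(Z) - 2 < 1) {
      stop("sample too short for tau_max", call. = FALSE)
    }
    res <- .parcorr(
      lag_data$L[, c(.cidx(i, lg, N), .cidx(j, 0L, N))],
      lag_data$L[, .cidx(Z$i, Z$lag, N), drop = FALSE]
    )
    rho[r] <- res[1]
    p[r] <- res[2]
    keep[r] <- res[2] <= alpha
  }
  links$rho <- rho
  links$p_value <- p
  links <- links[keep, , drop = FALSE]
  parents <- lapply(vn, function(v) {
    sel <- links$sink == v & links$orientation == "directed"
    sel0 <- links$lag == 0L & links$orientation != "directed" &
      (links$source == v | links$sink == v)
    other <- ifelse(links$source[sel0] == v, links$sink[sel0], links$source[sel0])
    tibble::tibble(
      parent = c(links$source[sel], other),
      lag = c(links$lag[sel], links$lag[sel0])
    )
  })
  names(parents) <- vn
  new_causal_graph(
    links = links, var_names = vn, tau_max = graph$tau_max,
    alpha = alpha, n_eff = lag_data$n_eff, parents = parents
  )
}

#' Run the full discovery engine
#'
#' Composition of [discover_skeleton()], [orient_links()] and
#' [mci_validate()]. Fully deterministic given the panel and parameters: the
#' engine contains no internal randomness.
#'
#' @inheritParams discover_skeleton
#' @return A `causal_graph`: the validated, lag-annotated link set with MCI
#'   partial correlations and p-values.
#' @examples
#' spec <- make_random_scm(3, cross_density = 0.2, lag_max = 2, seed = 1)
#' panel <- simulate_panel(spec, 400, seed = 2)
#' run_pcmciplus(panel, tau_max = 3, alpha = 0.01)
#' @export
run_pcmciplus <- function(panel, tau_max = 7, alpha = 0.05,
                          check_stationarity = FALSE) {
  sk <- discover_skeleton(panel, tau_max, alpha, check_stationarity)
  mci_validate(panel, orient_links(sk), alpha)
}

#' @importFrom generics tidy
#' @method tidy causal_graph
#' @export
tidy.causal_graph <- function(x, ...) {
  x$links
}

#' @importFrom generics glance
#' @method glance causal_graph
#' @export
glance.causal_graph <- function(x, ...) {
  tibble::tibble(
    n_vars = x$n_vars,
    n_links = nrow(x$links),
    n_contemporaneous = sum(x$links$lag == 0L),
    n_lagged = sum(x$links$lag >= 1L),
    n_unoriented = sum(x$links$orientation == "unoriented"),
    n_conflict = sum(x$links$orientation == "conflict"),
    tau_max = x$tau_max,
    alpha = x$alpha,
    n_eff = x$n_eff
  )
}

#' Score a discovered graph against a ground-truth graph
#'
#' Matches links by (source, sink, lag) identity; contemporaneous links are
#' matched as unordered pairs since their orientation is a separate question
#' from their detection. For each true link the detected flag, the matched
#' rho and whether its sign agrees with the planted coefficient are
#' reported; false alarms are the discovered links matching no true link.
#'
#' @param graph A discovered `causal_graph`.
#' @param truth The `causal_graph` from [true_graph()].
#' @return A tibble, one row per true link: `source`, `sink`, `lag`,
#'   `coeff`, `detected`, `rho_hat`, `sign_ok`; the number of false alarms
#'   is in the `n_false_alarms` attribute.
#' @export
score_graph_recovery <- function(graph, truth) {
  gl <- graph$links
  tl <- truth$links
  match_one <- function(src, snk, lg) {
    hit <- gl$lag == lg &
      ((gl$source == src & gl$sink == snk) |
        (lg == 0L & gl$source == snk & gl$sink == src))
    which(hit)[1]
  }
  rows <- purrr::map_dfr(seq_len(nrow(tl)), function(r) {
    m <- match_one(tl$source[r], tl$sink[r], tl$lag[r])
    tibble::tibble(
      source = tl$source[r], sink = tl$sink[r], lag = tl$lag[r],
      coeff = tl$rho[r],
      detected = !is.na(m),
      rho_hat = if (is.na(m)) NA_real_ else gl$rho[m],
      sign_ok = if (is.na(m)) NA else sign(gl$rho[m]) == sign(tl$rho[r])
    )
  })
  matched <- vapply(
    seq_len(nrow(gl)),
    function(r) {
      any(tl$lag == gl$lag[r] &
        ((tl$source == gl$source[r] & tl$sink == gl$sink[r]) |
          (gl$lag[r] == 0L & tl$source == gl$sink[r] & tl$sink == gl$source[r])))
    },
    logical(1)
  )
  attr(rows, "n_false_alarms") <- sum(!matched)
  rows
}

#' Read and write causal graphs as JSON
#'
#' Machine-readable link table: an object with `var_names`, `tau_max`,
#' `alpha`, `n_eff` and a `links` array of
#' `{source, sink, lag, p_value, rho, orientation}` records.
#'
#' @param graph A `causal_graph`.
#' @param path File path.
#' @return `read_graph_json()` returns a `causal_graph`.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(
    var_names = graph$var_names,
    tau_max = graph$tau_max,
    alpha = graph$alpha,
    n_eff = graph$n_eff,
    links = graph$links
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(graph)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  links <- tibble::as_tibble(obj$links)
  # columns that are entirely NA (e.g. the p-values of a ground-truth graph)
  # serialise as nulls and vanish on read; restore them
  defaults <- list(
    source = character(), sink = character(), lag = integer(),
    rho = numeric(), p_value = numeric(), orientation = character()
  )
  for (col in names(defaults)) {
    if (!col %in% names(links)) {
      links[[col]] <- rep(defaults[[col]][NA_integer_][1], nrow(links))
    }
  }
  links$lag <- as.integer(links$lag)
  new_causal_graph(
    links = links[, c("source", "sink", "lag", "rho", "p_value", "orientation")],
    var_names = obj$var_names,
    tau_max = obj$tau_max,
    alpha = obj$alpha,
    n_eff = obj$n_eff
  )
}
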