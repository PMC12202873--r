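#' Pipeline configuration
#'
#' A validated flat list of every tunable the end-to-end pipeline uses. The
#' defaults reproduce the analysis settings for the six-variable daily
#' panel: the nine calendar periods, delays 0-7, raw alpha 0.05 with no
#' multiple-testing correction, Granger lag orders 1-7, and the 30-cell
#' persistence grid.
#'
#' @param periods Seasonal-adjustment periods, days.
#' @param tau_max Maximum delay tested by the discovery engine.
#' @param alpha Significance level for link removal/retention.
#' @param granger_lags Lag orders for the Granger validation scan.
#' @param granger_sink Sink variable of the Granger scan (name), or `NULL`
#'   for the last panel column.
#' @param persistence_tau,persistence_alpha Robustness grid.
#' @param detrend_bandwidth Local-linear trend bandwidth, days.
#' @param seed Integer seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed governs any upstream simulation).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(periods = default_periods(),
                            tau_max = 7,
                            alpha = 0.05,
                            granger_lags = 1:7,
                            granger_sink = NULL,
                            persistence_tau = 5:14,
                            persistence_alpha = c(0.05, 0.01, 0.001),
                            detrend_bandwidth = 365,
                            seed = 1L) {
  cfg <- list(
    periods = as.numeric(periods),
    tau_max = as.integer(tau_max),
    alpha = as.numeric(alpha),
    granger_lags = as.integer(granger_lags),
    granger_sink = granger_sink,
    persistence_tau = as.integer(persistence_tau),
    persistence_alpha = as.numeric(persistence_alpha),
    detrend_bandwidth = as.numeric(detrend_bandwidth),
    seed = as.integer(seed)
  )
  if (!all(cfg$periods > 0)) stop("periods must be positive", call. = FALSE)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (cfg$tau_max < 1) stop("tau_max must be >= 1", call. = FALSE)
  if (!all(cfg$granger_lags >= 1)) {
    stop("granger_lags must be >= 1", call. = FALSE)
  }
  if (!all(cfg$persistence_alpha > 0 & cfg$persistence_alpha < 1)) {
    stop("persistence_alpha must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path A YAML file whose keys mirror the `pipeline_config()`
#'   arguments; missing keys take the defaults.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess (seasonal adjustment + detrend), the stationarity
#' report, the discovery engine, the link-persistence grid, and the Granger
#' validation scan on one input panel, writing `clean.csv`,
#' `stationarity.csv`, `graph.json`, `persistence.csv`, `granger.csv` and
#' `manifest.json` under `out_dir`. The input file is never modified, and a
#' rerun with the same input and config is byte-identical.
#'
#' @param input Path to a panel CSV (see [read_panel_csv()]).
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines?
#' @return The manifest, invisibly: config echo, input checksum, per-stage
#'   timings (seconds), output paths, package version, seed.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  say("reading panel from %s", input)
  panel <- stage("read", read_panel_csv(input))
  say(
    "preprocess: %d periods, bandwidth %g days",
    length(config$periods), config$detrend_bandwidth
  )
  clean <- stage("preprocess", preprocess_panel(
    panel,
    periods = config$periods, bandwidth = config$detrend_bandwidth
  ))
  paths <- list(
    clean = file.path(out_dir, "clean.csv"),
    stationarity = file.path(out_dir, "stationarity.csv"),
    graph = file.path(out_dir, "graph.json"),
    persistence = file.path(out_dir, "persistence.csv"),
    granger = file.path(out_dir, "granger.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_panel_csv(clean, paths$clean)
  say("stationarity gate at alpha %g", config$alpha)
  statrep <- stage("stationarity", stationarity_report(clean, config$alpha))
  readr::write_csv(statrep, paths$stationarity)
  say("discovery: tau_max %d, alpha %g", config$tau_max, config$alpha)
  graph <- stage("discover", run_pcmciplus(
    clean,
    tau_max = config$tau_max, alpha = config$alpha
  ))
  write_graph_json(graph, paths$graph)
  say(
    "persistence grid: %d x %d cells",
    length(config$persistence_tau), length(config$persistence_alpha)
  )
  pers <- stage("persistence", link_persistence(
    clean,
    tau_grid = config$persistence_tau,
    alpha_grid = config$persistence_alpha
  ))
  readr::write_csv(pers, paths$persistence)
  sink_var <- config$granger_sink %||% utils::tail(panel_vars(panel), 1)
  say("granger scan into %s, lags %s", sink_var,
    paste(range(config$granger_lags), collapse = "-"))
  gr <- stage("granger", granger_scan(clean, sink_var, config$granger_lags))
  readr::write_csv(gr, paths$granger)
  manifest <- list(
    package = "causalpanel",
    version = as.character(utils::packageVersion("causalpanel")),
    seed = config$seed,
    config = unclass(config),
    input = input,
    input_md5 = unname(tools::md5sum(input)),
    timings = timings,
    outputs = unlist(paths[setdiff(names(paths), "manifest")])
  )
  jsonlite::write_json(manifest, paths$manifest,
    digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  stopifnot(all(file.exists(unlist(paths))))
  invisible(manifest)
}
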