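#' Construct a daily time-series panel
#'
#' A panel is an ordinary tibble whose first column, `date`, holds a gap-free
#' strictly increasing daily calendar, followed by one numeric column per
#' variable. Every stage of the pipeline consumes and returns this shape, so
#' analyses compose with the pipe.
#'
#' @param x A data frame with a `date` column (or first column coercible to
#'   `Date`) and numeric variable columns.
#' @return A tibble of class `ts_panel` with `date` first.
#' @examples
#' as_ts_panel(data.frame(
#'   date = seq(as.Date("2019-01-01"), by = "day", length.out = 10),
#'   x = rnorm(10), y = rnorm(10)
#' ))
#' @export
as_ts_panel <- function(x) {
  x <- tibble::as_tibble(x)
  if (!ncol(x) >= 2) {
    stop("a panel needs a date column and at least one variable", call. = FALSE)
  }
  date_col <- if ("date" %in% names(x)) "date" else names(x)[1]
  dates <- x[[date_col]]
  if (!inherits(dates, "Date")) {
    dates <- tryCatch(as.Date(dates), error = function(e) {
      stop("first column is not parseable as ISO-8601 dates", call. = FALSE)
    })
    if (anyNA(dates)) {
      stop("first column is not parseable as ISO-8601 dates", call. = FALSE)
    }
  }
  vals <- x[setdiff(names(x), date_col)]
  panel <- dplyr::bind_cols(tibble::tibble(date = dates), vals)
  validate_ts_panel(panel)
  class(panel) <- c("ts_panel", class(tibble::tibble()))
  panel
}

#' @rdname as_ts_panel
#' @param panel Object to validate.
#' @export
validate_ts_panel <- function(panel) {
  stopifnot(is.data.frame(panel), "date" %in% names(panel))
  dates <- panel$date
  if (nrow(panel) < 2) stop("panel needs T >= 2 rows", call. = FALSE)
  if (anyDuplicated(dates)) {
    stop("duplicate timestamp: ", dates[duplicated(dates)][1], call. = FALSE)
  }
  gaps <- diff(as.integer(dates))
  if (any(gaps < 0)) stop("dates must be strictly increasing", call. = FALSE)
  if (any(gaps != 1L)) {
    at <- dates[which(gaps != 1L)[1]] + 1
    stop("calendar gap at ", format(at), call. = FALSE)
  }
  vars <- setdiff(names(panel), "date")
  if (anyDuplicated(vars)) stop("variable names must be unique", call. = FALSE)
  ok <- vapply(panel[vars], is.numeric, logical(1))
  if (!all(ok)) {
    stop("non-numeric variable column: ", vars[!ok][1], call. = FALSE)
  }
  if (anyNA(panel[vars])) stop("panel must have no missing values", call. = FALSE)
  invisible(panel)
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("# A daily panel: ", nrow(x), " days x ", ncol(x) - 1L, " variables (",
    format(min(x$date)), " to ", format(max(x$date)), ")\n",
    sep = ""
  )
  NextMethod()
}

panel_vars <- function(panel) setdiff(names(panel), "date")

panel_matrix <- function(panel) {
  as.matrix(panel[panel_vars(panel)])
}

#' Read and write panel CSV files
#'
#' Panels are stored as plain CSV with an ISO-8601 `date` column followed by
#' one numeric column per variable. Reading enforces the gap-free daily
#' calendar contract; a skipped day raises a calendar-gap error rather than
#' silently propagating misaligned lags downstream.
#'
#' @param path Path to a CSV file.
#' @param panel A `ts_panel` (or data frame passing [validate_ts_panel()]).
#' @return `read_panel_csv()` returns a `ts_panel`; `write_panel_csv()`
#'   returns `panel` invisibly.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_ts_panel(raw)
}

#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path) {
  validate_ts_panel(panel)
  out <- as.data.frame(panel)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' @describeIn as_ts_panel Line plot of every variable, faceted, for a quick
#'   visual check of seasonality, trends and spikes.
#' @param object A `ts_panel`.
#' @param ... Unused.
#' @method autoplot ts_panel
#' @export
autoplot.ts_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"date",
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL)
}
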