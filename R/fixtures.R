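#' Packaged advocacy-account reference list
#'
#' The twenty most-followed Twitter accounts of anti- and proregulation
#' firearm-advocacy organizations used to build the two tweet-count series:
#' nine antiregulation and eleven proregulation accounts, each with its
#' follower count and the number of posts containing the study keyword.
#' Follower counts printed in "k" units are stored as integers at the
#' printed x100 precision; the two fully printed counts are stored exactly.
#'
#' @return A tibble: `category`, `handle`, `organization`, `followers`,
#'   `posts`.
#' @examples
#' dplyr::count(load_account_fixture(), category)
#' @export
load_account_fixture <- function() {
  path <- system.file("extdata", "advocacy_accounts.csv",
    package = "causalpanel", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      category = readr::col_character(),
      handle = readr::col_character(),
      organization = readr::col_character(),
      followers = readr::col_integer(),
      posts = readr::col_integer()
    )
  )
}

#' Packaged reference link table
#'
#' The thirteen labelled links (a-m) of the published six-variable causal
#' graph: source, sink, delay in days, printed p-value, signed partial
#' correlation, and link persistence over the 30-cell robustness grid.
#' Censored p-values are kept verbatim in `p_value` ("<0.001"); `p_ceiling`
#' gives the numeric upper bound for computation. Variable codes follow
#' [study_variables()]. This table also parameterises [study_mimic_spec()].
#'
#' @return A tibble: `link`, `source`, `sink`, `lag`, `p_value`,
#'   `p_ceiling`, `rho`, `persistence`.
#' @export
load_link_fixture <- function() {
  path <- system.file("extdata", "reference_links.csv",
    package = "causalpanel", mustWork = TRUE
  )
  fx <- readr::read_csv(path,
    col_types = readr::cols(
      link = readr::col_character(),
      source = readr::col_character(),
      sink = readr::col_character(),
      lag = readr::col_integer(),
      p_value = readr::col_character(),
      rho = readr::col_double(),
      persistence = readr::col_double()
    )
  )
  fx$p_ceiling <- as.numeric(sub("^<", "", fx$p_value))
  fx[, c(
    "link", "source", "sink", "lag", "p_value", "p_ceiling",
    "rho", "persistence"
  )]
}
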