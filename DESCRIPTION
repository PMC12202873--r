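Package: causalpanel
Title: Causal Discovery for Daily Multivariate Time-Series Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based causal discovery on daily count
    panels: linear-Gaussian structural-causal simulation with known ground
    truth, harmonic seasonal adjustment and local-linear detrending with
    ADF/KPSS stationarity gating, PCMCI+ graph discovery with
    partial-correlation conditional-independence tests over lagged and
    contemporaneous links, momentary-conditional-independence validation,
    hyperparameter-grid link-persistence analysis, and pairwise Granger
    causality F-tests. All front-end functions take and return tibbles so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
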