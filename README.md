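# causalpanel

Constraint-based causal discovery for daily multivariate count panels.

Many questions in public health and computational social science come as a
small set of daily time series that plausibly drive one another — for
example, three media-coverage counts (firearm laws and regulation, mass
shootings, violent crime), the tweet counts of anti- and proregulation
advocacy organizations, and the FBI's NICS firearm background checks, a
standard daily proxy for firearm acquisition. `causalpanel` implements the
full analysis chain such a panel needs, for analysts who want lag-resolved
causal structure rather than a pile of pairwise correlations:

1. **Preprocessing to stationarity.** Harmonic-regression seasonal
   adjustment at the calendar periods of daily count data (1, 2, 3, 5, 7,
   30, 31, 365.25/12, 365.25 days), local-linear detrending, and a joint
   stationarity gate: the ADF unit-root test must reject
   (p < 0.05) and the KPSS level-stationarity test must *not* reject
   (p > 0.1).
2. **PCMCI+ graph discovery.** Over all candidate links
   X<sup>i</sup><sub>t−τ</sub> → X<sup>j</sup><sub>t</sub>, τ = 0…τ_max, a
   PC-stable condition-selection skeleton search (lagged phase, then a
   contemporaneous phase conditioned on the discovered lagged parents of
   both endpoints), collider/Meek orientation of lag-0 links, and momentary
   conditional independence (MCI) validation: each link is retested given
   the parents of both its sink and its (time-shifted) source, which
   controls the dependence inflation that autocorrelation induces. The
   conditional-independence test throughout is partial correlation ρ with
   the t-test p-value on n − |Z| − 2 degrees of freedom; the sign of ρ
   gives the direction of the association.
3. **Link persistence.** The discovery engine reruns over a 30-cell
   hyperparameter grid (τ_max = 5…14 × α ∈ {0.05, 0.01, 0.001}); a link's
   persistence is the fraction of cells in which it reappears at its exact
   lag.
4. **Granger validation.** Pairwise Granger-causality F-tests
   (restricted autoregressive model vs. full model with the source's lags,
   F = ((RSS_r − RSS_f)/L)/(RSS_f/(n − 2L − 1))) for every source into a
   chosen sink at lag orders 1…7.

Because real panels of this kind are one-shot observational data, the
package also ships a linear-Gaussian structural-causal simulator with known
ground truth (`scm_spec()`, `simulate_panel()`, `true_graph()`), including
`study_mimic_spec()`, a six-variable fixture whose 13 cross-links form
a reference media/advocacy/background-checks network, so that calibration
(false-positive rates on null panels) and recovery (recall, lag accuracy,
sign accuracy) can be measured instead of assumed.

All user-facing functions take a data frame first and return tibbles, so
analyses compose with the pipe; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate the six-variable study-mimic panel (2,923 days, with seasonal and
trend contamination), preprocess it, gate on stationarity, discover the
graph, and score it against the planted truth:

```r
library(causalpanel)

spec  <- study_mimic_spec(contaminated = TRUE)
panel <- simulate_panel(spec, n_days = 2923, seed = 42)
clean <- preprocess_panel(panel)
stationarity_report(clean)
#> # A tibble: 6 × 7
#>   variable          adf_stat    adf_p kpss_stat kpss_p kpss_p_bracket stationary
#>   <chr>                <dbl>    <dbl>     <dbl>  <dbl> <chr>          <lgl>
#> 1 media_laws           -34.4 0          0.0107     0.1 > 0.1          TRUE
#> 2 media_shootings      -35.4 0          0.0101     0.1 > 0.1          TRUE
#> 3 media_crime          -33.9 0          0.0148     0.1 > 0.1          TRUE
#> 4 tweets_anti          -36.5 0          0.0107     0.1 > 0.1          TRUE
#> 5 tweets_pro           -35.9 0          0.00887    0.1 > 0.1          TRUE
#> 6 background_checks    -15.8 1.05e-28   0.0120     0.1 > 0.1          TRUE
```

Every series passes the joint gate: the seasonal/trend contamination has
been removed. Now run the discovery engine at the default τ_max = 7,
α = 0.05 and compare with the planted network:

```r
graph <- run_pcmciplus(clean, tau_max = 7, alpha = 0.05)
score_graph_recovery(graph, true_graph(spec))
#> # A tibble: 13 × 7
#>    source            sink                lag  coeff detected rho_hat sign_ok
#>    <chr>             <chr>             <int>  <dbl> <lgl>      <dbl> <lgl>
#>  1 media_shootings   media_laws            1  0.094 TRUE      0.105  TRUE
#>  2 media_laws        media_crime           0  0.1   TRUE      0.0702 TRUE
#>  3 media_shootings   media_crime           1  0.083 TRUE      0.0606 TRUE
#>  4 media_crime       media_shootings      0  0.071 TRUE      0.0449 TRUE
#>  5 media_laws        tweets_pro            2 -0.069 TRUE     -0.0522 TRUE
#>  6 background_checks media_crime           1  0.105 TRUE      0.119  TRUE
#>  7 tweets_anti       media_crime           2  0.048 TRUE      0.0513 TRUE
#>  8 media_crime       background_checks     7 -0.075 TRUE     -0.0666 TRUE
#>  9 media_crime       background_checks     6  0.054 FALSE    NA      NA
#> 10 tweets_anti       background_checks     1  0.048 TRUE      0.0575 TRUE
#> 11 media_laws        background_checks     1  0.084 TRUE      0.113  TRUE
#> 12 background_checks media_laws            1  0.099 TRUE      0.0994 TRUE
#> 13 background_checks tweets_anti           2  0.059 TRUE      0.0596 TRUE
```

On this seed, 12 of the 13 planted links are recovered at their exact lag
with the correct sign; the one miss is the weakest high-lag link (|ρ| =
0.054 at lag 6). `rho_hat` is the MCI partial correlation the engine
assigns to each detected link. Granger validation into background checks
tells the same story — the strongest predictor is media coverage of
firearm laws:

```r
granger_scan(clean, "background_checks", lags = 1:7) |>
  dplyr::filter(p_value < 0.001) |>
  dplyr::arrange(dplyr::desc(f_stat)) |>
  head(5)
#> # A tibble: 5 × 10
#>   source     sink   lag_order f_stat  p_value rss_restricted rss_full n_used
#>   <chr>      <chr>      <int>  <dbl>    <dbl>          <dbl>    <dbl>  <int>
#> 1 media_laws backg…         1   50.6 1.42e-12          3079.    3026.   2922
#> 2 media_laws backg…         2   25.5 1.05e-11          3077.    3024.   2921
#> 3 media_laws backg…         3   17.2 4.50e-11          3075.    3022.   2920
#> 4 media_laws backg…         4   13.8 4.03e-11          3070.    3013.   2919
#> 5 media_laws backg…         5   10.9 1.94e-10          3069.    3012.   2918
```

The robustness sweep and the end-to-end pipeline (which writes `clean.csv`,
`stationarity.csv`, `graph.json`, `persistence.csv`, `granger.csv` and a
run manifest) are one call each:

```r
persistence <- link_persistence(clean)           # 30-cell grid
run_pipeline("panel.csv", "results/")            # the whole chain
```

A command-line wrapper with the same verbs is installed at
`system.file("cli", "causalpanel", package = "causalpanel")`.

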