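---
title: "Methods: causal discovery for daily count panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal discovery for daily count panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalpanel)
```

This vignette is the package's own account of its statistical machinery:
the model each stage assumes, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The inferential problem

The data are a daily panel: T consecutive calendar days by N count-like
series that plausibly influence one another at short lags — in the
motivating application, three media-coverage series, two advocacy-group
tweet-count series, and NICS firearm background checks, with
T = 2,923 days (2012-01-01 through 2020-01-01 inclusive). The goal is a
*lag-annotated directed graph*: which series drives which, at which delay
(0 to 7 days), with what sign and strength. Constraint-based discovery
(the PCMCI+ family) attacks this by testing conditional independencies
under three standard assumptions: causal sufficiency (no relevant
unmeasured daily driver), faithfulness, and the causal Markov condition.
Linear-Gaussian dependence is additionally assumed throughout, since the
conditional-independence test is partial correlation.

## Preprocessing

Raw daily counts are dominated by day-of-week cycles, holiday/annual
cycles, and slow trends, all of which fake cross-correlations. Two
deterministic operators remove them:

* **Seasonal adjustment** (`seasonal_adjust()`) subtracts the least-squares
  fit of an intercept plus one sine/cosine pair per period. The default
  periods, in days, are 1, 2, 3, 5, 7, 30, 31, 365.25/12 and 365.25 —
  sub-weekly structure, day-of-week, the two calendar month lengths, the
  mean synodic month, and the tropical year. Harmonic regression handles
  the non-integer periods naturally, is an orthogonal projection (hence
  idempotent, which the suite verifies to 1e-8), and costs 17 of ~2,900
  degrees of freedom. Two numerical details: a period equal to the
  1-day sampling interval aliases to a constant, so period 1 contributes
  only the intercept; and the sine term at the Nyquist period 2 is
  identically zero on an integer grid and is dropped before fitting.
* **Detrending** (`detrend()`) subtracts a locally weighted linear smooth
  with a 365-day bandwidth — wide enough to leave week-scale causal
  dynamics untouched, narrow enough to absorb multi-year drifts — then
  recentres the residual to exact zero mean. A global polynomial was
  rejected because the panels of interest have irregular regime-like
  drifts; a local-linear smooth tracks those without modelling them.

Whether preprocessing sufficed is *tested*, not assumed
(`stationarity_report()`): the ADF unit-root test (intercept, no trend
term since the series was just detrended, lag order by AIC up to
⌊12(T/100)^¼⌋, MacKinnon response-surface p-values) must reject at 0.05,
and the KPSS level-stationarity test (Bartlett/Newey–West long-run
variance with the automatic bandwidth of Hobijn et al.) must *fail* to
reject, i.e. land in the "> 0.1" bracket of the tabulated critical values.
Requiring both protects against opposite failure modes: ADF alone is
weak against near-unit roots, KPSS alone against over-differencing.
Because only four KPSS critical values are tabulated, its p-value is
reported primarily as a bracket; the point value is linear interpolation
inside the table, clamped to [0.01, 0.1] outside it. Series failing the
gate are flagged, never silently dropped — the analyst decides.

## The conditional-independence test

`parcorr_test(x, y, z)` regresses x and y each on an intercept plus the
conditioning columns, correlates the residuals (ρ), and refers
ρ·√((n−|Z|−2)/(1−ρ²)) to a t distribution on n−|Z|−2 degrees of freedom
(the intercept is counted). The suite verifies the estimator against two
independent oracles — the precision-matrix closed form −Ω₁₂/√(Ω₁₁Ω₂₂) on
the sample covariance, and the recursive partial-correlation formula — to
1e-8, plus symmetry, affine invariance, and nominal null rejection rates.

## The discovery engine

`run_pcmciplus()` composes three stages, all deterministic given the panel
and (τ_max, α); the engine contains no randomness.

**Skeleton** (`discover_skeleton()`), in two phases. Phase 1 prunes the
lagged candidates X<sup>i</sup><sub>t−τ</sub> → X<sup>j</sup><sub>t</sub>,
τ ≥ 1: at conditioning-set size s = 0, 1, 2, … every remaining link is
tested given the s strongest current *lagged* parents of its sink
(strength = |ρ| from the previous level; ties broken by variable index
then lag, so runs are order-independent and reproducible), links with
p > α are removed at level end (the "stable" variant: adjacencies are
frozen within a level), and the loop ends when no link has s other
parents. Phase 2 subjects the lag-0 pairs to the same levelled search over
contemporaneous neighbours, always additionally conditioned on the
phase-1 lagged parents of *both* endpoints. Keeping contemporaneous
neighbours out of the lagged conditioning sets is deliberate: a lag-0
neighbour may be a *child* of the sink, and conditioning on a common child
induces explaining-away that biases true lagged links toward zero (on the
study-mimic model this attenuates one planted link's partial correlation
from 0.088 to 0.055 — enough to matter at these effect sizes). Separating
sets are recorded when a lag-0 pair is removed.

**Orientation** (`orient_links()`). Lagged links are oriented
past→present. Contemporaneous links go through the collider rule — for an
unshielded triple i—k—j with k absent from the separating set of (i, j),
orient i→k←j — then the standard Meek propagation rules R1–R3 to fixpoint.
A link reached by no rule stays `"unoriented"`; contradictory rule
applications yield `"conflict"` (drawn like unoriented links). The plain
collider rule can misfire when the i–j dependence is weak enough to be
removed without the middle node in the separating set; conservative
majority-vote variants exist but are not used here, keeping the rule
exactly as stated.

**MCI validation** (`mci_validate()`). Every surviving link is retested
conditioning on the parents of its sink (minus the candidate) together
with the lagged parents of its source, time-shifted by the link's lag —
the momentary-conditional-independence construction that controls
autocorrelation-induced dependence inflation. "Parents" is taken
literally: the lagged adjacency plus contemporaneous links *oriented into*
the variable. Unoriented lag-0 neighbours remain candidate links but are
never conditioners, for the explaining-away reason above. Links with MCI
p ≤ α are retained, carrying the MCI ρ and p-value. No multiple-testing
correction is applied on top of the raw α — the robustness sweep below is
the intended control for threshold sensitivity.

Two sampling choices are worth stating. First, every test in a run —
skeleton and MCI — uses the single aligned row set t = 2τ_max+1 … T: the
MCI stage conditions on time-shifted source parents whose lags reach
2τ_max, and a single row set keeps the effective sample identical across
all tests in a run rather than drifting with each conditioning set.
Second, the effective sample size reported per test is exactly that row
count.

Known limitation: because unoriented contemporaneous neighbours are never
conditioned on, a spurious *lagged* link whose dependence flows purely
through a contemporaneous coupling of autocorrelated series can survive
MCI. The persistence sweep and the Granger scan are the designed
cross-checks; links that appear only at one grid cell or fail Granger
validation deserve suspicion.

## Robustness and validation

`link_persistence()` reruns the full engine over τ_max = 5…14 ×
α ∈ {0.05, 0.01, 0.001} (30 cells) and scores each link by the fraction of
cells in which a link with the same (source, sink, lag) reappears after
MCI. Orientation is ignored in the matching, because contemporaneous
orientation legitimately flips across hyperparameters. The denominator is
always the full grid size — even for links whose lag exceeds some cells'
τ_max, which can never contain them — so persistence values are comparable
across links; the attainable ceiling is reported alongside
(`max_attainable`) for transparency. Presence-after-MCI is the matching
event, the natural reading of "found by the algorithm at that cell".

`granger_scan()` validates links into a chosen sink with the classical
two-regression F-test at lag orders 1…7, both models fitted on the
identical row set (rows lost to the longest lag dropped once) so the
models nest and RSS_full ≤ RSS_restricted holds by construction; an
intercept is included in both models.

## The synthetic-data generator

`scm_spec()` defines a linear-Gaussian structural-causal process:
X<sub>t</sub><sup>j</sup> = Σ c·X<sub>t−τ</sub><sup>i</sup> +
a<sub>j</sub>X<sub>t−1</sub><sup>j</sup> + seasonal<sub>j</sub>(t) +
b<sub>j</sub>t + ε<sub>t</sub><sup>j</sup>, with contemporaneous terms
resolved in topological order (lag-0 acyclicity is enforced), stability
enforced via the companion-matrix spectral radius of the reduced-form lag
polynomial (< 1), and a discarded burn-in of 10·max(lag, 1) steps to kill
initialisation transients. All randomness is a pure function of the seed,
and the simulator never touches the session RNG state.

`study_mimic_spec()` is the six-variable fixture: its 13 cross-links are
exactly the packaged reference network's (source, sink, delay) triples
with the printed signed partial correlations used as regression weights,
plus an AR(1) self-coefficient of 0.4 on every variable — the reference
table reports only cross-links, and without self-dependence the MCI
machinery's autocorrelation control would go unexercised; 0.4 gives
day-scale memory comparable to media/count series without dominating the
dynamics. Innovation SDs are 1 for every variable: the reference analysis
does not report post-preprocessing marginal scales, and every inference
step is scale-invariant, so unit variance is the neutral choice. With
`contaminated = TRUE` the spec adds cosine seasonality of amplitude 0.5
innovation-SDs at each of the nine calendar periods plus a linear trend of
10⁻³ SD/day (≈ 3 SDs over the 8-year window) — strong enough that an
unpreprocessed panel fails the stationarity gate, realistic for
administrative count data. Cosine (not sine) carries the injected
seasonality because sine vanishes identically at the Nyquist period 2 on
integer days.

Planted coefficients are regression weights, *not* target partial
correlations — the two differ once conditioning sets vary — so recovery is
scored on detection at the exact lag and on sign, never on coefficient
equality. What the generator does not emulate: count-valued marginals
(inference operates on detrended real-valued residuals anyway),
heavy-tailed event spikes, regime switches, and measurement-delay
artefacts; passing the suite therefore demonstrates correctness and
calibration of the machinery under the linear-Gaussian model, not
robustness to every real-data pathology.

## Scales used by the test suite

The suite measures, among other things: false-positive calibration of the
full engine on null panels (N = 4, T = 500, 200 panels, α ∈ {0.05, 0.01};
the per-candidate-link rate must sit within a factor 2 of α), recovery of
the study-mimic network at the study's own length (T = 2,923, 50 seeds:
every planted link with |coefficient| ≥ 0.08 recovered at its exact lag in
≥ 80% of seeds, signs correct in ≥ 95% of detections), and the
stationarity gate on contaminated panels (50 seeds, all six variables pass
in ≥ 90%). These problem sizes keep each property measurable with
meaningful precision while the whole suite stays a desk-scale run;
`scripts/acceptance.R` recomputes the same quantities at comparable sizes
from a single command-line seed.

## Interpreting output on real panels

Discovered links are associations that survived a specific battery of
conditional-independence tests under the stated assumptions; causal
sufficiency in particular is untestable from the panel alone. A sensible
reading of a real-data result inspects, per link: the MCI ρ (sign and
size), the persistence over the grid, and the Granger F — and treats
contemporaneous links with extra caution when the underlying reporting
processes have day-scale recording delays, which can displace or fabricate
a one-day lag.
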