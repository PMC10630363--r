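---
title: "Empirical habitat suitability from out-plant trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical habitat suitability from out-plant trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empsuit)
```

# The approach

`empsuit` estimates climatic habitat suitability for a plant species from
the measured performance of experimental out-plants rather than from
occurrence records. The pipeline has four statistical stages, each of
which this vignette describes together with its assumptions, tunable
parameters and numerical conventions, followed by an account of the
synthetic-data generator that stands in for a field campaign.

# Station processing and gap-filling

Raw logs arrive as 10-minute records of air temperature (AT, °C),
rainfall (RF, mm per interval), relative humidity (RH, %) and volumetric
soil moisture (SM, m³/m³). Aggregation is strictly hierarchical:

* 10-minute → hourly: AT/RH/SM are averaged over the points present in
  the clock hour, RF is summed, and the contributing count is kept.
* hourly → daily: a local calendar day is *observed* only if at least 23
  hourly records are present (`min_hours = 23`); otherwise the whole day
  is missing. A near-complete day estimates the daily mean with
  negligible bias, while shorter fragments would alias the diurnal
  cycle.

Vapour pressure deficit is computed **hourly** as
`VPD = es(AT) · (1 − RH/100)` and only then averaged to daily. Because
the saturation curve `es` is convex in temperature, computing VPD from
daily mean AT would underestimate it systematically; the hourly route
avoids that. `es` uses the Lowe (1977) sixth-order polynomial over water
(hPa; constant term `es(0 °C) ≈ 6.1078`), hard-coded and unit-tested
against an independent power-sum evaluation.

Missing days are imputed station-by-station and variable-by-variable:

1. Donor candidates are ranked by the Pearson correlation of daily
   values on jointly observed days (`rank_donors()`), requiring at least
   `min_overlap = 3` joint days. Correlation is computed on raw daily
   values, not anomalies — with stations sharing one regional climate,
   the two orderings rarely differ, and raw values need no climatology
   model. Ties break by larger overlap, then lexically by station id, so
   rankings are deterministic.
2. Each missing day is filled with the OLS prediction from the
   best-ranked donor that has an observed value that day
   (`gap_fill()`). When the best donor is also missing, the next-ranked
   donor is tried (cascading); each filled value records the donor
   actually used. Leaving holes instead would bias period means toward
   the seasons that happened to be observed.
3. Rainfall gets two physical overrides: when the donor's daily total is
   exactly zero the filled value is zero (the *no-rain condition* —
   regression intercepts would otherwise manufacture drizzle on dry
   days), and any negative prediction is floored at 0.

Filling is idempotent: a complete series passes through unchanged.
Period summaries (`summarize_period()`) average daily values over a
window, reporting rainfall as mean daily total (mm/day) and the fraction
of covered days.

# Site-level performance

Survival is evaluated at a single assessment date. Death is absorbing —
a plant is dead iff a `dead` status was recorded on or before the date —
and a plant missed at one census but seen later is treated as alive
throughout, because deaths are recorded affirmatively. Plants of this
monocarpic species that flower and then die are counted as **living**:
death after reproduction is not stress-related, and counting it as
mortality would misattribute climate effects. Their growth rate uses the
final pre-flowering diameter.

Relative growth rate is the per-day change in log rosette area,
`(ln d_f² − ln d_i²)/days`; it is exactly 0 for no net growth and
negative for shrinkage. A site's mean RGR is reported only when at least
two plants survive — one measurement carries no site-level information —
and the flag `rgr_defined` makes the exclusion explicit.

`build_design()` reproduces the allocation structure of the trial: every
site receives the same number of plants (default 42: 14 from
mid-elevation and 28 from high-elevation maternal lines), with between 2
and 8 siblings per maternal line per site. Feasibility (per-line stock ≥
2 per site × sites; quotas within per-line bounds) is checked up front
and violations are reported with the constraint that failed. Within-site
planting order is randomised under a caller-supplied seed.

# Candidate models and AICc

Site-level responses (percent survival; mean RGR) are regressed on one
or two of the five climate summaries {AT, RF, RH, SM, VPD}, plus the
interaction for two-variable models. Pairs whose site-level correlation
exceeds `|r| > 0.7` are excluded before enumeration; the enumerator
accepts either a correlation matrix or an explicit exclusion list (with
the three exclusions used in the motivating study — RH·RF, RH·VPD,
RF·VPD — the candidate set has 5 + 7 + 7 = 19 members). Interactions use
raw, uncentered products: with only a handful of sites, centering
changes nothing about fit or ranking, only the intercept's
interpretation.

Models are ranked by the least-squares form of the small-sample Akaike
criterion,

```
AICc = n · ln(RSS/n) + 2k + 2k(k + 1)/(n − k − 1),
```

with `k` counting the intercept, all slopes, and the error variance.
Only AICc *differences* matter for ranking, so any self-consistent
constant convention is equivalent; this one is stated explicitly because
reported Δ values depend on `k`'s definition. Conventions for degenerate
cases: an exact fit (RSS = 0) scores −∞ and ranks first; fits too small
for the correction (`n ≤ k + 1`) carry `NA` and cannot be ranked; a
constant response defines R² = 0. The ranked table flags candidate sets
at Δ ≤ 2, Δ ≤ 4 and Δ ≤ 4.5 — the last because a model of interest may
sit just above the conventional cutoff and still merit retention on
explanatory-power and mappability grounds.

A logit-scale variant (`fit_logit_variant()`) fits OLS to
`logit(survival/100)` for comparison. It is deliberately flagged
non-default: the transform stretches sites near the survival bounds,
giving them influence out of proportion to their information content.
Responses exactly at 0 or 100 are rejected unless the caller opts into
the boundary adjustment `p → (x + 0.5)/(n + 1)` (with `x` the survivor
count), a standard empirical-logit shrinkage.

# Suitability mapping

The chosen survival model projects over gridded AT (°C) and RF (mm/day)
fields held in a `climate_grid` (row-major from the top-left, cell
membership by cell centre, equal-area cells; plain-text ESRI ASCII I/O).
Before projection, each raster layer is bias-corrected against the
station network: station values are regressed on co-located raster
values per station-year (≥ 3 pairs), and `corrected = slope · raster +
intercept` — i.e. the corrected raster predicts station-equivalent
values. The direction matters and is documented because the reverse
regression would not minimise error on the station scale.

The **relative climatic suitability index** is predicted percent
survival divided by 100, clamped to [0, 1], with per-cell clamp flags.
Clamping is idempotent and applied again after any arithmetic that could
leave the interval (extrapolation), so no non-nodata cell ever leaves
[0, 1] anywhere in the pipeline.

Historical change is estimated by regressing the index on window
end-year per cell (`fit_trend()`), over a series of multi-year windows
(the motivating design: six 57-month windows ending in October, five
years apart). With only six points per cell, the slope t-test is
underpowered, so significance is mapped at α = 0.1 and α = 0.2 rather
than 0.05; no serial-autocorrelation correction is applied (the short
series show little), and no multiple-testing correction is made across
cells — the maps display raw per-cell classes, which a reader should
interpret as descriptive. Conventions: constant series get slope 0 and
p = 1; cells with fewer than three non-missing periods are nodata.
Future maps extrapolate linearly from a base year (by default the final
historical window's end-year) and re-clamp.

`area_fraction()` summarises a map over a polygon as the cell-count
fraction above or > / at-or-below a threshold (default 0.7, a
demographic-stability benchmark); the two directions partition the cells
exactly.

# Occurrence-based comparison

The simplified SDM path mirrors standard practice: pseudo-absences are
sampled uniformly without replacement from grid cells whose centres lie
more than 250 m from any presence polygon; threshold metrics (TSS =
sensitivity + specificity − 1, Cohen's kappa) come from the 2×2 table
and ROC AUC from the Mann–Whitney rank statistic with ties counted half;
the operating threshold maximises TSS over all cutpoints (ties to the
lowest). Ensembles weight member predictions proportionally to TSS,
floored at zero — a model with no skill gets no vote — and normalised to
sum to one, so the ensemble always lies in the members' envelope. The
built-in base learner is a ridge-regularised logistic regression on the
two climate covariates; it exists so the ensemble path runs end to end,
and stronger learners plug in through the same `(train, newdata) →
scores` interface.

# The synthetic world

`synth_world()` builds the test bed: a 40 × 40 grid of 250-m cells
carrying a conical volcano; AT follows a fixed lapse rate (6.5 °C/km)
from a 24 °C sea-level mean, and RF follows a west–east orographic
gradient spanning 2–10 mm/day. Nine stations are placed at a 3 × 3
factorial of AT (~7–13 °C) and RF targets, which keeps the two
predictors only weakly correlated across sites — the property the real
site network was designed for, and the one that makes both slopes
estimable from nine points. Default drifts (+0.03 °C/yr, −0.02
mm/day/yr) emulate a warming, drying climate; through the survival
model's chain rule they imply a known true suitability trend per cell,
recorded in the truth object.

The weather generator produces daily station values as seasonal cycle +
shared regional AR(1) anomaly + site noise (the shared term, weight
0.95, induces the high inter-station correlations that make regression
gap-filling work), and rainfall as regionally shared wet days (35 % of
days) with exponential intensities and site multipliers — so a dry donor
day almost always means a dry target day, making the no-rain condition
approximately true by construction. Ten-minute records add a ±2 °C
diurnal cycle, small jitter, and rainfall distributed over random
bursts; `gen_daily_network()` emits the same daily process directly for
workflows that never touch sub-daily data. Survival probabilities at the
default sites span ~0.05–1 under the default generating model, so both
survival extremes and the clamp are exercised; with the generating
model's predictions exceeding 100 % at the coolest, wettest sites, the
realised site probabilities saturate there, and fits to realised
survival recover attenuated slopes — visible in the worked example and
expected of any bounded response. Out-plant monitoring emulates
twice-yearly censuses with post-transplant shrinkage then
stabilisation, and ~2 % of survivors at high-suitability sites flower
late in the study to exercise the flowered-as-living rule. Raster series
can inject an affine station-vs-raster distortion so bias correction is
testable against known parameters.

What the generator does *not* emulate: topographically structured
rainfall events, sensor drift and miscalibration, microsite (edaphic)
effects on survival independent of climate, spatial autocorrelation in
the raster noise beyond a 3 × 3 smoothing, and non-linear survival
responses. Passing tests therefore demonstrate the pipeline's
correctness and statistical calibration under its own assumptions — not
that a two-variable linear model suffices for any particular real
landscape.

# Problem sizes and determinism

Every generator is a pure function of its parameters and a seed, fanned
out internally to per-component substreams. The test suite runs the
station network at daily resolution over 6–12-month windows (ten-minute
generation is exercised over a two-month window), the trend-calibration
suite over 1000 synthetic cells × 6 windows, and Monte-Carlo properties
at 500 simulations — sizes chosen so the full suite completes in about a
minute while leaving the Monte-Carlo error small relative to the
tolerances tested.

# Known limitations

* Suitability is relative, tied to the trial's window and cohort; the
  index transfers across landscapes only insofar as relative survival
  does.
* Site-level OLS with n ≈ 9 cannot separate more than two climate
  effects; the collinearity screen makes that explicit rather than
  hiding it in variance inflation.
* Linear trend extrapolation decades forward inherits the linearity
  assumption and ignores raster non-stationarity; re-clamping bounds the
  damage but cannot repair it.
* The gap-filler assumes stationary inter-station relationships; a
  station whose relationship to its donors changes (vegetation growth,
  sensor drift) will be filled with the historical relationship.
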