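---
title: "Methods: heat exposure and preterm birth — models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat exposure and preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The scientific problem

Preterm birth (PTB, birth before 37 completed gestational weeks) has been
repeatedly associated with short-term heat exposure. Three questions
structure the analysis this package implements for daily warm-season
(May–September) time series:

1. **Total effect** — how much does the daily PTB rate rise on hot days,
   controlling for season, long-term trend and shared-weather confounders
   (solar radiation, wind speed, precipitation)?
2. **Natural direct effect** — how much of that association remains after
   excluding the pathways through air-pollutant mediators (ozone, PM10,
   NO2), whose concentrations themselves rise with temperature?
3. **Effect modification** — is the heat–PTB association stronger, on the
   additive scale that matters for public health, among mothers with
   independent PTB risk factors (black race, ages 16–19 or 30+, late/no
   prenatal care, smoking, no high-school education)?

## 2. Exposure: apparent temperature

Apparent temperature `AT = −2.653 + 0.994·T + 0.0153·Td²` (°C) combines
air temperature and humidity (via dew point Td) into one thermal-stress
metric. It is affine in `T` with slope 0.994 and monotone in `Td` for
`Td ≥ 0`; negative dew points are legal and enter as the signed value
squared, exactly as the formula states. The analysis exposure is the mean
of AT on the day of and the day before birth (`at2_c`).

Numerical conventions worth stating because they move printed values:

* **Lags before restriction.** Lag means are computed on the full
  calendar series and the May–September restriction is applied
  afterwards, so 1 May uses 30 April exposure. The exposure definition
  has no season truncation of its own.
* **Percentiles.** The p50/p95 contrast uses linear interpolation
  between order statistics (`quantile` type 7); a different convention
  shifts the contrast by ~0.1 °C.
* **Precipitation log offset 1 mm.** Around half of warm-season days are
  rain-free, so `ln(x)` is undefined; `ln(x + 1)` is used. PM10 and NO2
  use offset 0 with a 0.5-unit floor guard.
* **Station backfill.** Primary-station days that are missing are filled
  from a secondary station with per-day provenance flags; days missing at
  both stations remain missing (counted and logged) and are dropped by
  the downstream models.

## 3. Total-effect model

Daily counts are fit by Poisson regression with log link:
intercept; cubic b-spline in day-of-year (interior knots at equally
spaced quantiles; 2, 5 or 8 knots in replication mode); cubic b-spline in
integer year index (2 interior knots, replaced by year indicator dummies
when the study has too few distinct years for the basis); a
piecewise-linear AT term — linear slope plus hinge `max(0, AT2 − k)` —
and the confounders. The hinge knot `k` defaults to the empirical median,
the fixed rule standing in for the original visual nonlinearity
screening; a b-spline diagnostic fit (`exposure_response_table`) plays
the role of the exposure–response curve.

Open choices resolved here:

* *Knots vs degrees of freedom.* The source description conflates the
  two; replication mode treats the number (2/5/8) as interior-knot count.
  The stability-across-settings property is what matters and is what the
  acceptance suite asserts (AF span < 3 percentage points on
  smooth-seasonality data).
* *Year term.* A spline over the integer year index (not continuous
  date), because the seasonal spline already carries within-year shape.
* *Bootstrap.* Days are resampled i.i.d. with replacement; the contrast
  temperatures and the hinge location are frozen at their full-data
  values inside resamples so every resample estimates the same contrast.
  A moving-block option (default block 7 days) exists for autocorrelation
  sensitivity. Percentile intervals; resamples whose refit fails are
  skipped and counted, >5 % failures is an error.
* *Overdispersion.* The Pearson dispersion statistic is recorded on
  every fit; the Poisson likelihood is retained for the main models.

`AF = (1 − 1/RR) × 100`. The formula sometimes printed as
`1/(1 − RR) × 100` is negative for any RR > 1 and inconsistent with every
tabulated RR→AF pair it accompanies; it is available behind
`literal = TRUE` for documentation only.

## 4. Imputation of missing pollutants

Chained equations over the three pollutant columns, predictors = lags
0–2 of {AT, solar, wind, ln precip, O3, ln PM10, ln NO2} (21 columns; a
pollutant's own lag-0 column is excluded from its model). Draws are plain
normal-error regression predictions — not predictive-mean matching —
because the imputed variables are log-scale near-Gaussian; PM10 and NO2
are imputed on the log scale and back-transformed, and observed cells are
restored bit-for-bit. Two burn-in sweeps precede m = 3 retained sweeps.
Convergence is tracked by a logged between-sweep drift statistic rather
than visual trace plots. With `noise_scale = 0` the chain is iterated to
its fixed point (tolerance 1e-10), which makes the deterministic-limit
oracle exact and the between-imputation variance exactly zero — the two
properties the unit tests assert. The PTB outcome is deliberately **not**
in the imputation model (exposure-side variables only); run-boundary days
whose lagged predictors do not exist are mean-filled in the predictor
matrix only.

## 5. Mediation by inverse odds weighting

Stage 1 regresses `at2_c` on the lag 0–1 means of the mediators plus the
confounders; `σ²` is the model mean squared error. Stage 2 refits the
total-effect design (no pollutants) weighted. Two weight schemes ship,
and the difference between them is the package's most consequential
design decision:

* **`literal_eq1`** (default, fidelity): `w = 1/exp(Â/σ²)`, the formula
  exactly as printed in the source method. It does not depend on the
  observed exposure, which differs from published inverse-odds-weighting
  derivations; whether that is a simplification or a typesetting loss is
  unknowable from the text, so it is implemented verbatim, not
  "corrected". Its statistical behaviour is documented, not asserted.
* **`density_ratio`** (the scheme under which recovery properties are
  asserted): `w = f̂(A|C)/f̂(A|M,C)` with normal densities from two
  regressions. Two additions were necessary to make this estimator
  behave, both decided on statistical grounds:
  1. a day-of-year spline (4 interior knots) joins the confounder set of
     both exposure regressions — season dominates apparent temperature,
     and the scheme's validity rests on `f̂(A|C)` being well specified;
  2. log-weights are symmetrically truncated at their 1st/99th
     percentiles before normalisation — standard inverse-probability
     weight stabilisation. Without it a handful of far-tail days
     dominate the weighted fit (effective sample sizes were observed to
     collapse from ~1700 to ~30 and single-seed indirect AFs to swing by
     ±15 percentage points on data with no mediated effect at all).

All weights are computed in log space and normalised to mean one; the
weighted Poisson coefficients are invariant to the common scale (asserted
to 1e-8), so the normalisation is presentational, not substantive.

Pooling: total and direct effects are estimated per completed dataset and
averaged; indirect = pooled total − pooled direct, exactly. The bootstrap
re-runs *both* stages (exposure model, weights, weighted fit) inside each
resample so the interval carries weight-estimation uncertainty; resampled
day indices are shared across the m completed datasets within a resample.
Whether the original analysis resampled before or after imputation is
unstated; resampling completed datasets jointly was chosen because it
keeps the imputation fixed exactly where the observed data are fixed.

## 6. Additive effect modification (RERI)

The data are expanded to one row per date × realized combination of the
six maternal indicators, zero-count rows materialised (the two age
indicators never co-occur: a three-level age variable encoded as two
dummies). A negative-binomial model — dispersion by maximum likelihood,
Poisson fallback when the dispersion estimate sits at the boundary —
shares the seasonal/year splines across strata and includes, per
modifier, a main effect plus interactions with both the linear and the
hinge AT terms. For modifier EM,

    RERI = RR(AT=p95, EM=1) − RR(AT=p95, EM=0) − RR(AT=p50, EM=1) + 1,

all three against the common (p50, EM = 0, all other modifiers = 0)
denominator. CIs come from a date-cluster bootstrap (all strata of a date
move together, preserving within-date sums in every resample).

One estimand subtlety deserves emphasis: with no at-risk denominator
(none exists in a cases-only design), the fitted modifier main effect is
the *count* rate ratio, which equals the population-share ratio times the
per-capita risk ratio. The synthetic generator therefore calibrates its
interaction slopes against exactly this estimand (share ratio included;
`uniroot`, tolerance 1e-8), so "calibrated RERI = 0.5" means the value
the model is consistent for — this is also why RERI magnitudes from such
designs are reported as qualitative (sign and order), not as per-capita
interaction sizes. Missingness in indicator variables, when present in
real records, becomes an explicit level excluded from RERI contrasts so
date-sum conservation survives.

## 7. Case-crossover sensitivity analysis

Time-stratified referents: the calendar is partitioned into fixed 2- or
3-week blocks anchored at the first study date (calendar months for the
month rule); a case day's referents are the other days of its stratum,
weekday-matched by default (conventional, to control weekly patterns —
an assumption, switchable). Estimation maximises the conditional
(stratified Cox, Breslow) likelihood with each matched set weighted by
the day's case count; with one case per set this equals exact conditional
logistic regression. The OR is reported at the same p95-vs-p50 AT
contrast as the time-series RR.

Known limitation, stated plainly: with aggregate daily counts, this
count-weighted conditional likelihood is a conditional Poisson
likelihood, i.e. it consistently estimates the *same rate ratio* as the
time-series model. The classical "ORs exceed RRs when the outcome is
common" phenomenon requires individual-level binary outcomes with an
at-risk denominator, which a cases-only design does not carry. The
package therefore treats OR-vs-RR comparisons as qualitative; the
acceptance suite measures the comparison honestly and the corresponding
criterion is expected to reflect sampling noise, not systematic OR
inflation.

## 8. The synthetic-data generator

The generator is the stated world against which everything is validated.
Per seeded scenario it produces:

* **Meteorology** — temperature as an annual sinusoid (mean 11 °C,
  amplitude 10 °C, peak day 199) plus AR(1) noise (coefficient 0.7,
  innovation SD 1.6 °C: realistic synoptic persistence); dew point =
  temperature − Gamma(2, 2.6) depression (dew point ≤ temperature by
  construction); log-normal wind; seasonal solar radiation;
  zero-inflated-gamma precipitation (47 % wet days). These defaults were
  tuned once so the warm-season exposure summaries land near the
  published ones (simulated AT2 median ≈ 18.8 °C vs printed 18.6; p95 ≈
  25.7 vs 24.9; solar ≈ 207 vs 218 W/m²; geometric-mean precipitation
  ≈ 0.5 vs 0.4 mm) — rough agreement, exact matching not attempted
  since only summary statistics of the original meteorology are public.
* **Pollutants** — linear in 2-day-mean AT plus solar/wind terms and
  Gaussian noise, floored at 1; intercepts tuned to the published means
  (O3 ≈ 44.5 vs 44.8 ppb; PM10 geometric mean ≈ 39.4 vs 39.0 µg/m³;
  NO2 ≈ 18.5 vs 18.4 ppb); per-pollutant MCAR masking at
  `missing_frac`.
* **Births** — per date × indicator-stratum counts, Poisson or negative
  binomial, log mean = baseline (log 5 ≈ the published 9053 births over
  11 warm seasons) + seasonal term (peak-to-trough 0.2, peak day 175,
  matching the observed early-summer PTB maximum) + hinge AT effect +
  pollutant terms (evaluated on unmasked concentrations) + modifier main
  effects + calibrated interaction slopes. The season window is
  day-of-year 121–273 mapped through a non-leap reference calendar, so
  it is 1 May – 30 September in every year.

Scenario presets: `null` (no effects), `no_mediation` (true RR 1.12 at
the p95-vs-p50 contrast, no pollutant effects), `mediation` (direct RR
1.10 plus an ozone-mediated path, `gamma_o3 = 0.004`/ppb — total RR
above direct by construction), `interaction` (modifier main effects and
RERI targets with one protective and several risk-enhancing modifiers,
mirroring the qualitative pattern reported for this population).
The truth block records the realized percentiles, the calibrated slope,
true direct/total RRs and AFs, and the implied per-modifier RERIs.

What the generator does **not** emulate — hence what a green test does
not establish: spatial exposure misclassification (one "city-wide"
series, no stations-versus-residence geography); within-pregnancy
exposure history and gestational-age-at-risk structure (daily counts, no
cohort denominator); correlated mediator noise beyond their shared
temperature response; informative (non-MCAR) pollutant missingness;
individual-level covariate correlation between the six indicators
(independent prevalences, except the structural age exclusivity).
Recovery on this world shows the estimators are consistent for their
estimands under the stated model, not that the original study's numbers
are right.

## 9. Seeds, budgets and degenerate inputs

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state; identical (config, seed) reproduces byte-identical
datasets and CSVs. Acceptance-suite simulation sizes follow the stated
reductions (bootstrap 200/250 instead of 500/1000; the RERI fixture is
scaled to 3 years and a single active modifier) to keep the suite inside
its runtime budget. Degenerate inputs fail loudly and specifically:
all-missing pollutant columns, missing meteorology, rank-deficient
designs (collinear columns named), hinge knots outside the observed
range, sigma² at the interpolation floor, > 5 % failed bootstrap
resamples, contradictory age indicators, strata without referents
(dropped and counted).
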