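# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# analysis-ready series from a synthetic dataset (lags computed before the
# warm-season restriction, per the pipeline convention)
prep_series <- function(ds) {
  s <- prepare_daily_series(ds$weather, ds$pollutants)
  s <- restrict_warm_season(s)
  s[!is.na(s$at2_c), , drop = FALSE]
}

aligned_counts <- function(ds, series) {
  cd <- daily_counts(ds$births)
  cd$count[match(series$date, cd$date)]
}

# default no_mediation world (true RR 1.12 at the p95-vs-p50 contrast)
fix_no_mediation <- function() {
  fixture("no_mediation", function() {
    ds <- simulate_dataset(scenario_config("no_mediation", n_years = 11, seed = 42))
    s <- prep_series(ds)
    list(ds = ds, series = s, counts = aligned_counts(ds, s))
  })
}

fix_null <- function() {
  fixture("null", function() {
    ds <- simulate_dataset(scenario_config("null", n_years = 11, seed = 43))
    s <- prep_series(ds)
    list(ds = ds, series = s, counts = aligned_counts(ds, s))
  })
}

# single-modifier interaction fixture calibrated to RERI = 0.5 for smokers;
# scaled to 3 years so the bootstrap suites stay inside the time budget
smoker_only <- function(x) c(black = 0, age16_19 = 0, age30plus = 0,
                             low_prenatal = 0, smoker = x, no_hs = 0)

fix_interaction_config <- function(seed) {
  scenario_config("interaction", n_years = 3, seed = seed,
                  modifier_prevalences = smoker_only(0.25),
                  reri_targets = smoker_only(0.5),
                  modifier_log_rr = smoker_only(0.25),
                  dispersion = 0.15, beta0 = log(8))
}
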