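# synthetic_data: generator contracts, determinism and truth consistency

test_that("scenario configs validate their fields", {
  expect_error(scenario_config(n_years = 0), "n_years")
  expect_error(scenario_config(missing_frac = 1), "missing_frac")
  expect_error(scenario_config(modifier_prevalences = c(
    black = 1.2, age16_19 = 0.2, age30plus = 0.2, low_prenatal = 0.3,
    smoker = 0.2, no_hs = 0.3)), "prevalences")
  expect_error(scenario_config(modifier_prevalences = c(
    black = 0.5, age16_19 = 0.6, age30plus = 0.6, low_prenatal = 0.3,
    smoker = 0.2, no_hs = 0.3)), "age16_19")
  expect_error(scenario_config(beta_at = -0.1), "beta_at")
  expect_error(scenario_config(ar1 = 1), "ar1")
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- scenario_config("mediation", n_years = 2, seed = 99,
                         missing_frac = 0.15)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$weather, d2$weather)
  expect_identical(d1$pollutants, d2$pollutants)
  expect_identical(d1$births, d2$births)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(scenario_config("mediation", n_years = 2, seed = 100,
                                         missing_frac = 0.15))
  expect_false(identical(d1$weather, d3$weather))
})

test_that("degenerate generator settings give a constant temperature series", {
  cfg <- scenario_config("null", n_years = 1, seed = 1, temp_amp_c = 0,
                         ar_sd = 0)
  w <- generate_weather(cfg)
  expect_equal(diff(range(w$temp_c)), 0)
})

test_that("the calendar covers the season window every year, plus warm-up", {
  cfg <- scenario_config("null", n_years = 11, seed = 1)
  w <- generate_weather(cfg)
  per_year <- table(format(w$date, "%Y"))
  expect_equal(length(per_year), 11L)
  # 153 season days (1 May - 30 Sep) + 2 warm-up days, leap or not
  expect_true(all(per_year == 153L + 2L))
  expect_true(all(w$dewpoint_c <= w$temp_c))
  expect_true(all(w$precip_mm >= 0))
})

test_that("pollutants respond to temperature, and missingness is MCAR", {
  cfg0 <- scenario_config("no_mediation", n_years = 7, seed = 5,
                          alpha_at_to_pollutant = c(o3 = 0, pm10 = 0, no2 = 0),
                          pollutant_solar = c(o3 = 0, pm10 = 0, no2 = 0),
                          pollutant_wind = c(o3 = 0, pm10 = 0, no2 = 0))
  w <- generate_weather(cfg0)
  p0 <- generate_pollutants(w, cfg0)
  at2 <- prepare_daily_series(w)$at2_c
  ok <- !is.na(at2)
  # null construction: correlation within Monte-Carlo error of zero
  expect_lt(abs(cor(p0$complete$o3_ppb[ok], at2[ok])), 3 / sqrt(sum(ok)))
  expect_false(any(is.na(p0$observed$o3_ppb)))

  cfg1 <- scenario_config("no_mediation", n_years = 7, seed = 5,
                          missing_frac = 0.15)
  p1 <- generate_pollutants(generate_weather(cfg1), cfg1)
  n <- nrow(p1$observed)
  n_miss <- sum(p1$mask$pm10_ugm3)
  expect_lt(abs(n_miss - 0.15 * n), 3 * sqrt(n * 0.15 * 0.85))
  expect_equal(is.na(p1$observed$pm10_ugm3), p1$mask$pm10_ugm3)

  expect_error(generate_pollutants(w[-1, ], cfg0), "alignment")
})

test_that("null scenario counts match exp(beta0) and tables align", {
  cfg <- scenario_config("null", n_years = 11, seed = 17,
                         seasonal_amplitude = 0)
  ds <- simulate_dataset(cfg)
  cd <- daily_counts(ds$births)
  expect_gte(nrow(cd), 1000L)
  # mean daily count = exp(beta0) within 3 standard errors
  se <- sd(cd$count) / sqrt(nrow(cd))
  expect_lt(abs(mean(cd$count) - exp(cfg$beta0)), 3 * se)
  expect_true(all(ds$births$count >= 0))
  expect_true(all(ds$births$count == round(ds$births$count)))
  # identical gap-free date index within the season window
  season_weather <- restrict_warm_season(ds$weather)
  expect_identical(sort(unique(ds$births$date)), season_weather$date)
  expect_identical(ds$pollutants$date, ds$weather$date)
  # age indicators never co-occur
  expect_equal(sum(ds$births$age16_19 * ds$births$age30plus), 0L)
})

test_that("truth block is algebraically consistent with the generator", {
  f <- fix_no_mediation()
  tr <- f$ds$truth
  expect_equal(tr$rr_direct,
               exp(tr$beta_at * (tr$at_p95 - tr$at_p50)))
  expect_equal(tr$rr_direct, 1.12)         # calibrated target
  expect_equal(tr$rr_total, tr$rr_direct)  # no mediated pathway
  expect_equal(tr$af_indirect, 0)

  ds_med <- simulate_dataset(scenario_config("mediation", n_years = 2, seed = 3))
  expect_gt(ds_med$truth$rr_total, ds_med$truth$rr_direct)
})

test_that("interaction calibration is solvable and errors when impossible", {
  cfg <- fix_interaction_config(1)
  ds <- simulate_dataset(cfg)
  expect_equal(unname(ds$truth$reri_implied["smoker"]), 0.5, tolerance = 1e-7)
  expect_true(ds$truth$interaction_slopes[["smoker"]] > 0)
  # an absurdly negative target makes the implied RR11 non-positive
  bad <- scenario_config("interaction", n_years = 1, seed = 1,
                         modifier_prevalences = smoker_only(0.25),
                         reri_targets = smoker_only(-5),
                         modifier_log_rr = smoker_only(0))
  expect_error(simulate_dataset(bad), "unattainable")
})

test_that("datasets round-trip to CSV plus truth JSON", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(scenario_config("null", n_years = 1, seed = 2))
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("weather.csv", "pollutants.csv", "births.csv", "truth.json"))
  w <- read.csv(file.path(dir, "weather.csv"), colClasses = c(date = "Date"))
  expect_equal(w$temp_c, ds$weather$temp_c, tolerance = 1e-12)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(tr$rr_direct, ds$truth$rr_direct)
})
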