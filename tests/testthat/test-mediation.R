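# mediation_iow: exposure model, inverse odds weights, direct effects,
# decomposition and pooling

test_that("exposure model: null mediators, degenerate fit guard", {
  # mediators generated independent of AT: coefficients within 3 SE of 0
  cfg <- scenario_config("no_mediation", n_years = 8, seed = 51,
                         alpha_at_to_pollutant = c(o3 = 0, pm10 = 0, no2 = 0),
                         pollutant_solar = c(o3 = 0, pm10 = 0, no2 = 0),
                         pollutant_wind = c(o3 = 0, pm10 = 0, no2 = 0))
  s <- prep_series(simulate_dataset(cfg))
  em <- fit_exposure_model(s)
  # z-scores via a plain lm refit for standard errors
  mm <- cbind(heatptb:::.mediator_means(s),
              s[, c("solar_wm2", "wind_ms", "ln_precip")], at = s$at2_c)
  lmfit <- lm(at ~ ., data = mm)
  z <- summary(lmfit)$coefficients[c("o3_01", "ln_pm10_01", "ln_no2_01"), "t value"]
  expect_true(all(abs(z) < 3))
  expect_gt(em$sigma2, 0)

  # AT an exact linear function of a mediator: sigma2 floor triggers
  s2 <- fix_no_mediation()$series
  s2 <- add_mediator_means(s2)
  s2$at2_c <- 2 * s2$o3_01
  expect_error(fit_exposure_model(s2), "sigma2 below floor|interpolate")
})

test_that("mediation fixture: exposure model recovers the pollutant slope geometry", {
  f <- fixture("mediation_ds", function() {
    ds <- simulate_dataset(scenario_config("mediation", n_years = 8, seed = 52))
    list(ds = ds, series = prep_series(ds))
  })
  em <- fit_exposure_model(f$series)
  expect_gt(em$coefficients[["o3_01"]], 0)
})

test_that("literal weights follow the printed formula, then normalise to mean 1", {
  # constant prediction: all weights exactly 1
  s <- fix_no_mediation()$series
  s <- add_mediator_means(s)
  em <- fit_exposure_model(s)
  em0 <- em
  em0$coefficients[] <- 0
  w0 <- inverse_odds_weights(em0, s, "literal_eq1")
  expect_equal(as.numeric(w0), rep(1, nrow(s)))

  # a single day predicted at sigma2, zero elsewhere: that day's weight is
  # e^-1 times the others' (pre-normalisation ratio survives normalisation)
  em1 <- em
  em1$coefficients[] <- 0
  em1$coefficients[["o3_01"]] <- 1
  s1 <- s
  s1$o3_01 <- c(em1$sigma2, rep(0, nrow(s) - 1))
  w1 <- inverse_odds_weights(em1, s1, "literal_eq1")
  expect_equal(w1[1] / w1[2], exp(-1), tolerance = 1e-12)
  expect_equal(mean(w1), 1)
})

test_that("density-ratio weights are near one when mediators carry no information", {
  cfg <- scenario_config("no_mediation", n_years = 8, seed = 53,
                         alpha_at_to_pollutant = c(o3 = 0, pm10 = 0, no2 = 0),
                         pollutant_solar = c(o3 = 0, pm10 = 0, no2 = 0),
                         pollutant_wind = c(o3 = 0, pm10 = 0, no2 = 0))
  s <- prep_series(simulate_dataset(cfg))
  em <- fit_exposure_model(s, season_knots = 4)
  w <- inverse_odds_weights(em, s, "density_ratio")
  expect_lt(sd(w), 0.1)
  expect_lt(max(abs(w - 1)), 0.5)
})

test_that("all-ones weights make the direct estimate equal the total estimate", {
  f <- fix_no_mediation()
  s <- add_mediator_means(f$series)
  q <- exposure_percentiles(s$at2_c)
  contrast <- c(q[["p50"]], q[["p95"]])
  total <- bootstrap_effect(s, f$counts, n_boot = 0, contrast = contrast)
  direct <- estimate_direct(s, f$counts, rep(1, nrow(s)), contrast = contrast)
  expect_equal(direct$rr, total$rr, tolerance = 1e-12)
  expect_equal(direct$af_percent, total$af_percent, tolerance = 1e-12)
})

test_that("decompose_and_pool is exact arithmetic with contract errors", {
  p1 <- decompose_and_pool(10.6, 10.4)
  expect_equal(p1$indirect_af, 10.6 - 10.4)
  expect_equal(p1$m_pooled, 1L)
  p3 <- decompose_and_pool(c(9, 9, 9), c(7, 7, 7))
  expect_equal(p3$total_af, 9)
  expect_equal(p3$indirect_af, 2)
  pm <- decompose_and_pool(c(10, 12, 11), c(9, 10, 8))
  expect_equal(pm$total_af, 11)
  expect_equal(pm$direct_af, 9)
  expect_equal(pm$indirect_af, 2)
  expect_error(decompose_and_pool(1:3, 1:2), "pooling error")
})

test_that("mediate: identity, pooling and bootstrap determinism", {
  f <- fix_no_mediation()
  med <- mediate(f$series, f$counts, scheme = "literal_eq1", n_boot = 10,
                 seed = 6)
  expect_equal(med$indirect_af, med$total_af - med$direct_af)
  med2 <- mediate(f$series, f$counts, scheme = "literal_eq1", n_boot = 10,
                  seed = 6)
  expect_identical(med$cis, med2$cis)
  expect_equal(med$m_pooled, 1L)
  # identical datasets across m pool to the single-dataset estimate
  med3 <- mediate(list(f$series, f$series, f$series), f$counts,
                  scheme = "literal_eq1", n_boot = 0)
  expect_equal(med3$total_af, med$total_af)
  expect_equal(med3$indirect_af, med$indirect_af)
})
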