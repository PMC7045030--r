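# effect_modification: stratum expansion, NB interaction model, RERI

test_that("expand_strata materialises zero rows and conserves daily totals", {
  d <- as.Date("1995-07-01")
  births <- data.frame(
    date = rep(c(d, d + 1), each = 2),
    black = c(1, 0, 1, 0), age16_19 = 0, age30plus = c(0, 1, 0, 1),
    low_prenatal = 0, smoker = c(1, 0, 1, 0), no_hs = 0,
    count = c(3L, 2L, 0L, 4L))
  out <- expand_strata(births)
  # 2 realized combos x 2 dates, zero rows materialised
  expect_equal(nrow(out), 4L)
  expect_equal(sum(out$count), sum(births$count))
  daily_in <- tapply(births$count, births$date, sum)
  daily_out <- tapply(out$count, out$date, sum)
  expect_equal(as.numeric(daily_out), as.numeric(daily_in))

  # per-birth records (no count column) aggregate to the same structure
  rec <- births[rep(seq_len(4), births$count), names(births) != "count"]
  out2 <- expand_strata(rec)
  expect_equal(sum(out2$count), sum(births$count))

  bad <- births; bad$age16_19[2] <- 1  # row 2 already has age30plus = 1
  expect_error(expand_strata(bad), "validation error")
})

test_that("stratum shares track the configured prevalence", {
  # effect-free generator: the smoker count share is the prevalence
  cfg <- scenario_config("null", n_years = 3, seed = 7,
                         modifier_prevalences = smoker_only(0.25))
  ds <- simulate_dataset(cfg)
  strata <- expand_strata(ds$births)
  share <- sum(strata$count[strata$smoker == 1]) / sum(strata$count)
  n <- sum(strata$count)
  expect_lt(abs(share - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("no-modifier-effect generator gives null interaction terms", {
  cfg <- scenario_config("no_mediation", n_years = 4, seed = 71,
                         modifier_prevalences = smoker_only(0.3))
  ds <- simulate_dataset(cfg)
  s <- prep_series(ds)
  strata <- expand_strata(ds$births)
  fit <- suppressMessages(fit_interaction_model(strata, s))
  for (term in c("smoker_x_at", "smoker_x_hinge")) {
    z <- fit$coefficients[[term]] / sqrt(fit$vcov[term, term])
    expect_lt(abs(z), 3)
  }
})

test_that("zero-dispersion generator: NB agrees with Poisson", {
  cfg <- scenario_config("no_mediation", n_years = 3, seed = 72,
                         modifier_prevalences = smoker_only(0.3),
                         dispersion = 0)
  ds <- simulate_dataset(cfg)
  s <- prep_series(ds)
  strata <- expand_strata(ds$births)
  fit_nb <- suppressMessages(fit_interaction_model(strata, s))
  # Poisson benchmark on the identical design
  base <- build_design(s[match(strata$date, s$date), ], model_spec())
  at <- s$at2_c[match(strata$date, s$date)]
  X <- cbind(base$X, smoker = strata$smoker,
             smoker_x_at = strata$smoker * at,
             smoker_x_hinge = strata$smoker * pmax(0, at - base$at_knot))
  pois <- glm.fit(X, strata$count, family = poisson())
  if (is.finite(fit_nb$theta)) {
    # dispersion near the boundary: huge theta, coefficients match Poisson
    expect_gt(fit_nb$theta, 50)
  }
  expect_equal(unname(fit_nb$coefficients), unname(pois$coefficients),
               tolerance = 1e-3)
})

test_that("RERI identities hold exactly", {
  expect_equal(reri_from_rr(1, 1, 1), 0)
  expect_equal(reri_from_rr(2.0, 1.5, 1.2), 0.3)
  f <- fixture("reri_fit", function() {
    cfg <- fix_interaction_config(11)
    ds <- simulate_dataset(cfg)
    s <- prep_series(ds)
    fit <- suppressMessages(fit_interaction_model(expand_strata(ds$births), s))
    q <- exposure_percentiles(s$at2_c)
    list(fit = fit, q = q, truth = ds$truth)
  })
  r <- compute_reri(f$fit, "smoker", f$q[["p95"]], f$q[["p50"]])
  expect_equal(r$reri, reri_from_rr(r$rr11, r$rr10, r$rr01))
  expect_error(compute_reri(f$fit, "black", 25, 19), "contract error")
})

test_that("the calibrated smoker interaction is recovered", {
  f <- fixture("reri_fit", function() stop("built above"))
  r <- compute_reri(f$fit, "smoker", f$q[["p95"]], f$q[["p50"]])
  # truth 0.5 by numerical calibration; generous finite-sample band
  expect_lt(abs(r$reri - f$truth$reri_implied[["smoker"]]), 0.35)
})

test_that("the date-cluster bootstrap preserves within-date sums and is seeded", {
  cfg <- fix_interaction_config(12)
  ds <- simulate_dataset(cfg)
  s <- prep_series(ds)
  strata <- expand_strata(ds$births)
  # resampling unit is the date: mirror the internal index construction
  dates <- sort(unique(strata$date))
  by_date <- split(seq_len(nrow(strata)), match(strata$date, dates))
  set.seed(1)
  pick <- sample.int(length(dates), length(dates), replace = TRUE)
  idx <- unlist(by_date[pick], use.names = FALSE)
  res <- strata[idx, ]
  n_combo <- nrow(unique(strata[, heatptb:::.modifier_names]))
  expect_true(all(table(res$date) %% n_combo == 0))
  orig_sum <- tapply(strata$count, strata$date, sum)
  res_first <- tapply(res$count, res$date, sum) /
    (table(res$date) / n_combo)
  expect_equal(as.numeric(res_first), as.numeric(orig_sum[names(res_first)]))

  tab1 <- suppressMessages(bootstrap_reri(strata, s, n_boot = 8, seed = 3))
  tab2 <- suppressMessages(bootstrap_reri(strata, s, n_boot = 8, seed = 3))
  expect_identical(tab1$ci_lower, tab2$ci_lower)
  expect_s3_class(tab1, "reri_table")
})
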