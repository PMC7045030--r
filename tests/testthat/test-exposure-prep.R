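# exposure_prep: apparent temperature, backfill, lags, transforms,
# season restriction and percentiles

test_that("apparent temperature matches the published formula", {
  expect_equal(apparent_temperature(0, 0), -2.653)
  expect_equal(apparent_temperature(30, 20), 33.287)
  expect_equal(apparent_temperature(10, -5), 7.6695)
  # affine in T at fixed dew point, slope 0.994 exactly
  grid <- expand.grid(t = seq(-10, 35, by = 5), td = seq(-15, 25, by = 5))
  expect_equal(apparent_temperature(grid$t + 1, grid$td) -
                 apparent_temperature(grid$t, grid$td),
               rep(0.994, nrow(grid)))
  # monotone non-decreasing in dew point for td >= 0
  td <- seq(0, 25, by = 0.5)
  expect_true(all(diff(apparent_temperature(rep(20, length(td)), td)) >= 0))
  # non-finite input propagates as missing
  expect_true(is.na(apparent_temperature(NA, 5)))
  expect_true(is.na(apparent_temperature(5, Inf)))
  expect_error(apparent_temperature(1:3, 1:2), "same length")
})

test_that("station backfill keeps primary, fills from secondary, counts double-missing", {
  dates <- as.Date("2000-06-01") + 0:99
  prim <- data.frame(date = dates, temp_c = rnorm(100, 20))
  sec <- data.frame(date = dates, temp_c = rnorm(100, 19))

  # primary complete: output identical to primary
  out <- backfill_station(prim, sec)
  expect_equal(out$temp_c, prim$temp_c)
  expect_true(all(out$temp_c_src == "primary"))

  # primary all-missing: output equals secondary
  prim2 <- prim; prim2$temp_c <- NA_real_
  out2 <- backfill_station(prim2, sec)
  expect_equal(out2$temp_c, sec$temp_c)
  expect_true(all(out2$temp_c_src == "secondary"))

  # 11% missing at random, secondary complete: nothing missing after fill
  set.seed(7)
  prim3 <- prim
  holes <- sample(100, 11)
  prim3$temp_c[holes] <- NA_real_
  out3 <- backfill_station(prim3, sec)
  expect_equal(sum(is.na(out3$temp_c)), 0L)
  expect_equal(sum(out3$temp_c_src == "secondary"), 11L)
  expect_equal(out3$temp_c[-holes], prim$temp_c[-holes])

  # missing at both stations stays missing, is counted, not an error
  sec4 <- sec; sec4$temp_c[holes[1]] <- NA_real_
  out4 <- backfill_station(prim3, sec4)
  expect_equal(sum(is.na(out4$temp_c)), 1L)
  expect_equal(unname(attr(out4, "missing_both")["temp_c"]), 1L)
})

test_that("lag_mean maps day d to the mean over the lag window", {
  expect_equal(lag_mean(c(10, 20)), c(NA, 15))
  expect_equal(lag_mean(rep(3.5, 10))[-1], rep(3.5, 9))
  expect_equal(lag_mean(1:5, lags = 0), as.numeric(1:5))  # identity
  expect_equal(lag_mean(c(1, 2, 4, 8), lags = c(1, 2)), c(NA, NA, 1.5, 3))
  d <- as.Date("2000-01-01") + 0:4
  expect_error(lag_mean(1:5, dates = rev(d)), "sorted")
  expect_error(lag_mean(1:5, dates = d[c(1, 1, 2, 3, 4)]), "duplicated")
  expect_error(lag_mean(1:5, dates = d[c(1, 2, 3, 4, 5)] + c(0, 0, 0, 5, 5)), "gap")
})

test_that("log transform handles offsets, floors and errors", {
  expect_equal(log_transform_skewed(0, offset = 1), 0)
  expect_equal(log_transform_skewed(exp(1) - 1, offset = 1), 1)
  expect_equal(log_transform_skewed(39.0), log(39.0), tolerance = 1e-12)
  expect_equal(round(log_transform_skewed(39.0), 4), 3.6636)
  expect_equal(log_transform_skewed(0, floor = 0.5), log(0.5))
  expect_error(log_transform_skewed(-2, offset = 1), "undefined")
})

test_that("warm-season restriction keeps May through September", {
  yr <- data.frame(date = seq(as.Date("1995-01-01"), as.Date("1995-12-31"), 1),
                   x = 1)
  out <- restrict_warm_season(yr)
  expect_equal(nrow(out), 153L)
  expect_identical(restrict_warm_season(out), out)
  empty <- yr[0, ]
  expect_equal(nrow(restrict_warm_season(empty)), 0L)
})

test_that("exposure percentiles use linear interpolation and guard small n", {
  q <- exposure_percentiles(1:100)
  expect_equal(unname(q["p50"]), 50.5)
  qc <- exposure_percentiles(rep(4.2, 30))
  expect_equal(unname(qc), c(4.2, 4.2))
  expect_error(exposure_percentiles(1:10), "at least 20")
})

test_that("the calibrated fixture reproduces the published exposure medians", {
  f <- fix_no_mediation()
  q <- exposure_percentiles(f$series$at2_c)
  expect_lt(abs(q[["p50"]] - 18.6), 1)    # printed median 18.6 C
  expect_lt(abs(q[["p95"]] - 24.9), 1.5)  # printed p95 24.9 C
})

test_that("lags are computed before the season restriction", {
  # 1 May must use 30 April exposure, so restricting first would differ
  f <- fix_no_mediation()
  w <- f$ds$weather
  s_full <- prepare_daily_series(w)
  may1 <- s_full$date[format(s_full$date, "%m-%d") == "05-01"][1]
  i <- which(s_full$date == may1)
  expect_equal(s_full$at2_c[i], mean(s_full$at_c[c(i - 1, i)]))
  # restricting first loses the 30 April history
  s_restr <- prepare_daily_series(restrict_warm_season(w))
  expect_true(is.na(s_restr$at2_c[s_restr$date == may1]))
})
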