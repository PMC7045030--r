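# total_effects: design construction, Poisson fit, RR/AF, bootstrap

test_that("the b-spline basis is a partition of unity with the right dimension", {
  x <- seq(1, 153, by = 1)
  B5 <- bspline_basis(x, 5)
  B8 <- bspline_basis(x, 8)
  expect_equal(rowSums(B5), rep(1, length(x)))
  expect_equal(ncol(B5), 5 + 3 + 1)
  expect_equal(ncol(B8) - ncol(B5), 3L)
})

test_that("the design matrix encodes the hinge and maps every term", {
  f <- fix_no_mediation()
  s <- f$series
  spec <- model_spec(doy_knots = 5)
  d <- build_design(s, spec)
  expect_equal(unname(d$X[, "at_hinge"]), pmax(0, s$at2_c - d$at_knot))
  expect_equal(sum(d$X[abs(s$at2_c - d$at_knot) < 1e-12, "at_hinge"]), 0)
  expect_setequal(names(d$map),
                  c("intercept", "doy", "year", "at_lin", "at_hinge", "covariates"))
  d8 <- build_design(s, model_spec(doy_knots = 8))
  expect_equal(length(d8$map$doy) - length(d$map$doy), 3L)
  # collinear covariates are named in the error
  s_bad <- s; s_bad$wind_ms <- s_bad$solar_wm2
  expect_error(build_design(s_bad, spec), "collinear")
  # hinge must sit inside the observed range
  expect_error(build_design(s, model_spec(at_knot_c = max(s$at2_c) + 1)),
               "inside the observed AT range")
})

test_that("the Poisson fit recovers closed forms and the generator's slope", {
  # intercept-only closed form: coefficient = log(mean count)
  y <- rep(7L, 50)
  design1 <- list(X = cbind(`(Intercept)` = rep(1, 50)),
                  map = list(intercept = 1L), at_knot = 0, at_range = c(-1, 1))
  fit1 <- fit_count_model(y, design1)
  expect_equal(unname(fit1$coefficients), log(7), tolerance = 1e-8)

  # null scenario: hinge coefficient within 3 SE of zero
  fn <- fix_null()
  dn <- build_design(fn$series, model_spec())
  fitn <- fit_count_model(fn$counts, dn)
  z <- fitn$coefficients["at_hinge"] / sqrt(fitn$vcov["at_hinge", "at_hinge"])
  expect_lt(abs(z), 3)

  # parameter recovery: calibrated slope inside 3 SE over 11 seasons
  f <- fix_no_mediation()
  d <- build_design(f$series, model_spec())
  fit <- fit_count_model(f$counts, d)
  beta_true <- f$ds$truth$beta_at
  se <- sqrt(fit$vcov["at_hinge", "at_hinge"])
  expect_lt(abs(fit$coefficients["at_hinge"] - beta_true), 3 * se)
})

test_that("relative risk follows the piecewise-linear closed form", {
  f <- fix_no_mediation()
  d <- build_design(f$series, model_spec())
  fit <- fit_count_model(f$counts, d)
  expect_equal(relative_risk(fit, 20, 20), 1.0)
  b_lin <- fit$coefficients[["at_lin"]]
  b_h <- fit$coefficients[["at_hinge"]]
  k <- fit$at_knot
  expect_equal(relative_risk(fit, k + 2, k), exp(2 * b_lin + 2 * b_h))
  expect_warning(relative_risk(fit, fit$at_range[2] + 5, k), "outside")
})

test_that("attributable fraction arithmetic and monotonicity", {
  expect_equal(attributable_fraction(1), 0)
  expect_equal(round(attributable_fraction(1.11), 1), 9.9)
  expect_equal(attributable_fraction(2), 50)
  expect_error(attributable_fraction(0), "positive")
  # literal printed form is negative above RR = 1, kept for documentation
  expect_lt(attributable_fraction(1.11, literal = TRUE), 0)
  # strictly increasing in RR, approaching 100
  grid <- attributable_fraction(seq(0.1, 50, length.out = 200))
  expect_true(all(diff(grid) > 0))
  expect_gt(attributable_fraction(1e6), 99.99)
})

test_that("weights scale out of the likelihood and bootstrap is seeded", {
  f <- fix_no_mediation()
  d <- build_design(f$series, model_spec())
  w <- runif(nrow(d$X), 0.5, 2)
  fit_a <- fit_count_model(f$counts, d, weights = w)
  fit_b <- fit_count_model(f$counts, d, weights = 7.3 * w)
  expect_equal(fit_a$coefficients, fit_b$coefficients, tolerance = 1e-8)

  est0 <- bootstrap_effect(f$series, f$counts, n_boot = 0)
  expect_true(all(is.na(est0$ci_af)))
  est1 <- bootstrap_effect(f$series, f$counts, n_boot = 20, seed = 4)
  est2 <- bootstrap_effect(f$series, f$counts, n_boot = 20, seed = 4)
  expect_identical(est1$ci_af, est2$ci_af)
  expect_equal(est1$rr, est0$rr)
  # moving-block variant runs and stays seeded
  estb <- bootstrap_effect(f$series, f$counts, n_boot = 10, seed = 4, block = 7)
  expect_false(any(is.na(estb$ci_af)))
})
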