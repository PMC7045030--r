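# Synthetic-data generator: seeded daily meteorology, mediating pollutants
# and stratified preterm-birth counts with a recoverable ground truth.
#
# The real outcome data (birth certificates) are confidential, so every
# downstream stage is exercised against this generator, whose data-generating
# truth (direct/total relative risks and attributable fractions at the
# 95th-vs-50th percentile exposure contrast, per-modifier additive
# interactions) is recorded alongside the data.

.modifier_names <- c("black", "age16_19", "age30plus", "low_prenatal",
                     "smoker", "no_hs")

.named6 <- function(x, what) {
  if (length(x) == 1L) x <- stats::setNames(rep(x, 6L), .modifier_names)
  if (is.null(names(x))) names(x) <- .modifier_names
  if (!setequal(names(x), .modifier_names)) {
    stop(what, " must be named by the six maternal indicators: ",
         paste(.modifier_names, collapse = ", "))
  }
  x[.modifier_names]
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles every data-generating parameter: the simulated calendar, the
#' meteorology process, the pollutant-on-temperature slopes, the baseline
#' and temperature effect on the log daily preterm-birth rate, maternal
#' modifier prevalences and main effects, additive-interaction targets,
#' pollutant missingness and count overdispersion.
#'
#' Four named scenarios set the effect parameters:
#' \describe{
#'   \item{null}{no temperature, pollutant or interaction effects.}
#'   \item{no_mediation}{a direct heat effect calibrated so the true
#'     relative risk at the 95th-vs-50th percentile contrast is
#'     `rr_target` (default 1.12); pollutants carry no effect.}
#'   \item{mediation}{a direct heat effect (true direct RR 1.10) plus an
#'     ozone-mediated pathway (`gamma_o3 = 0.004` per ppb), so the true
#'     total RR exceeds the true direct RR.}
#'   \item{interaction}{the no_mediation world plus modifier main effects
#'     and per-modifier additive-interaction (RERI) targets with the
#'     qualitative pattern seen in practice: one protective modifier,
#'     the rest risk-enhancing.}
#' }
#'
#' @param scenario one of `"null"`, `"no_mediation"`, `"mediation"`,
#'   `"interaction"`
#' @param n_years number of simulated warm seasons (default 11)
#' @param start_year first calendar year
#' @param season_days day-of-year window retained for analysis (default
#'   121-273, i.e. May through September)
#' @param warmup_days extra days generated before the window so lag means
#'   are defined from the first season day
#' @param beta0 baseline log daily count
#' @param rr_target true direct relative risk at the 95th-vs-50th
#'   percentile contrast; converted internally to a log-linear slope above
#'   the threshold. Ignored when `beta_at` is given.
#' @param beta_at log-RR per degree C of two-day-mean apparent temperature
#'   above the threshold (overrides `rr_target`)
#' @param at_threshold_c hinge location; default the simulated median
#' @param gamma_o3,gamma_pm10,gamma_no2 log-rate per unit pollutant
#' @param alpha_at_to_pollutant named slopes of each pollutant on two-day
#'   mean apparent temperature
#' @param seasonal_amplitude peak-to-trough seasonal term on the log rate
#' @param rate_peak_doy day-of-year at which the seasonal rate peaks
#' @param modifier_prevalences named probabilities of the six maternal
#'   indicators (the two age indicators never co-occur)
#' @param modifier_log_rr named log rate ratios (main effects) per modifier
#' @param reri_targets named per-modifier additive-interaction magnitudes at
#'   the 95th-vs-50th contrast; attained by numerically solving for the
#'   stratum-specific excess log rate (tolerance 1e-8)
#' @param missing_frac fraction of pollutant days masked missing completely
#'   at random
#' @param dispersion negative-binomial overdispersion (0 = Poisson)
#' @param temp_mean_c,temp_amp_c,temp_peak_doy annual temperature sinusoid
#' @param ar1,ar_sd AR(1) coefficient and innovation SD of daily
#'   temperature noise (default persistence 0.7)
#' @param dew_shape,dew_scale gamma parameters of the dew-point depression
#'   (guarantees dew point below air temperature)
#' @param solar_mean,solar_amp,solar_sd,wind_meanlog,wind_sdlog,rain_prob,rain_shape,rain_scale
#'   remaining meteorology parameters
#' @param pollutant_intercept,pollutant_solar,pollutant_wind,pollutant_noise_sd
#'   named pollutant regression parameters
#' @param seed integer RNG seed; the full dataset is reproducible from it
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(scenario = c("no_mediation", "null", "mediation",
                                         "interaction"),
                            n_years = 11L, start_year = 1991L,
                            season_days = c(121L, 273L), warmup_days = 2L,
                            beta0 = log(5),
                            rr_target = NULL, beta_at = NULL,
                            at_threshold_c = NULL,
                            gamma_o3 = NULL, gamma_pm10 = 0, gamma_no2 = 0,
                            alpha_at_to_pollutant = c(o3 = 1.6, pm10 = 1.0,
                                                      no2 = 0.35),
                            seasonal_amplitude = 0.2, rate_peak_doy = 175,
                            modifier_prevalences = c(black = 0.71,
                                                     age16_19 = 0.20,
                                                     age30plus = 0.27,
                                                     low_prenatal = 0.33,
                                                     smoker = 0.26,
                                                     no_hs = 0.39),
                            modifier_log_rr = 0,
                            reri_targets = 0,
                            missing_frac = 0, dispersion = 0,
                            temp_mean_c = 11, temp_amp_c = 10,
                            temp_peak_doy = 199, ar1 = 0.7, ar_sd = 1.6,
                            dew_shape = 2, dew_scale = 2.6,
                            solar_mean = 140, solar_amp = 100,
                            solar_sd = 45,
                            wind_meanlog = log(3.4), wind_sdlog = 0.42,
                            rain_prob = 0.47, rain_shape = 0.55,
                            rain_scale = 4.5,
                            pollutant_intercept = c(o3 = 10, pm10 = 25,
                                                    no2 = 15),
                            pollutant_solar = c(o3 = 0.04, pm10 = 0.01,
                                                no2 = 0.005),
                            pollutant_wind = c(o3 = -1.0, pm10 = -1.2,
                                               no2 = -0.8),
                            pollutant_noise_sd = c(o3 = 9, pm10 = 11,
                                                   no2 = 5.5),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario, n_years = as.integer(n_years),
    start_year = as.integer(start_year),
    season_days = as.integer(season_days), warmup_days = as.integer(warmup_days),
    beta0 = beta0, rr_target = rr_target, beta_at = beta_at,
    at_threshold_c = at_threshold_c,
    gamma_o3 = gamma_o3, gamma_pm10 = gamma_pm10, gamma_no2 = gamma_no2,
    alpha_at_to_pollutant = alpha_at_to_pollutant,
    seasonal_amplitude = seasonal_amplitude, rate_peak_doy = rate_peak_doy,
    modifier_prevalences = .named6(modifier_prevalences, "modifier_prevalences"),
    modifier_log_rr = .named6(modifier_log_rr, "modifier_log_rr"),
    reri_targets = .named6(reri_targets, "reri_targets"),
    missing_frac = missing_frac, dispersion = dispersion,
    temp_mean_c = temp_mean_c, temp_amp_c = temp_amp_c,
    temp_peak_doy = temp_peak_doy, ar1 = ar1, ar_sd = ar_sd,
    dew_shape = dew_shape, dew_scale = dew_scale,
    solar_mean = solar_mean, solar_amp = solar_amp, solar_sd = solar_sd,
    wind_meanlog = wind_meanlog, wind_sdlog = wind_sdlog,
    rain_prob = rain_prob, rain_shape = rain_shape, rain_scale = rain_scale,
    pollutant_intercept = pollutant_intercept,
    pollutant_solar = pollutant_solar, pollutant_wind = pollutant_wind,
    pollutant_noise_sd = pollutant_noise_sd,
    seed = as.integer(seed)
  )

  # scenario presets (only applied where the caller left the default)
  if (is.null(cfg$rr_target) && is.null(cfg$beta_at)) {
    cfg$rr_target <- switch(scenario, null = 1, no_mediation = 1.12,
                            mediation = 1.10, interaction = 1.12)
  }
  if (is.null(cfg$gamma_o3)) {
    cfg$gamma_o3 <- if (scenario == "mediation") 0.004 else 0
  }
  if (scenario == "interaction" && all(cfg$reri_targets == 0)) {
    cfg$reri_targets <- c(black = -0.3, age16_19 = 0.5, age30plus = 0.34,
                          low_prenatal = 0.44, no_hs = 0.19, smoker = 0.52)[.modifier_names]
    cfg$modifier_log_rr <- c(black = 0.5, age16_19 = 0.2, age30plus = 0.15,
                             low_prenatal = 0.25, no_hs = 0.1, smoker = 0.25)[.modifier_names]
  }
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  bad <- function(field, msg) stop("invalid scenario config field '", field, "': ", msg)
  if (cfg$n_years < 1L) bad("n_years", "must be >= 1")
  if (length(cfg$season_days) != 2L || cfg$season_days[1] >= cfg$season_days[2])
    bad("season_days", "must be an increasing day-of-year pair")
  pv <- cfg$modifier_prevalences
  if (any(pv < 0 | pv > 1)) bad("modifier_prevalences", "must lie in [0, 1]")
  if (pv["age16_19"] + pv["age30plus"] > 1)
    bad("modifier_prevalences", "age16_19 + age30plus must not exceed 1")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1)
    bad("missing_frac", "must lie in [0, 1)")
  if (cfg$dispersion < 0) bad("dispersion", "must be >= 0")
  if (!is.null(cfg$rr_target) && cfg$rr_target <= 0) bad("rr_target", "must be positive")
  if (!is.null(cfg$beta_at) && cfg$beta_at < 0)
    bad("beta_at", "must be >= 0 (heat is modelled as a risk factor)")
  if (cfg$ar1 < 0 || cfg$ar1 >= 1) bad("ar1", "must lie in [0, 1)")
  invisible(cfg)
}

scenario_dates <- function(cfg) {
  # day-of-year window mapped through a fixed non-leap reference calendar,
  # so the window is the same month-days (1 May - 30 Sep by default) in
  # every simulated year, leap or not
  doy <- seq(cfg$season_days[1] - cfg$warmup_days, cfg$season_days[2])
  md <- format(as.Date("2001-01-01") + (doy - 1L), "%m-%d")
  out <- lapply(seq_len(cfg$n_years) - 1L, function(k) {
    as.Date(paste0(cfg$start_year + k, "-", md))
  })
  do.call(c, out)
}

#' Generate daily warm-season meteorology
#'
#' Temperature is an annual sinusoid plus AR(1) noise (default persistence
#' 0.7, restarted each season); dew point is temperature minus a
#' gamma-distributed depression, so dew point never exceeds temperature;
#' wind is log-normal; solar radiation is a seasonal sinusoid plus noise;
#' precipitation is zero-inflated gamma. Fully reproducible from the seed.
#'
#' @param config a [scenario_config()]
#' @return data frame: `date`, `temp_c`, `dewpoint_c`, `wind_ms`,
#'   `solar_wm2`, `precip_mm`
#' @export
generate_weather <- function(config) {
  validate_scenario_config(config)
  dates <- scenario_dates(config)
  doy <- day_of_year(dates)
  n <- length(dates)
  with_seed(config$seed, {
    seasonal <- config$temp_mean_c +
      config$temp_amp_c * cos(2 * pi * (doy - config$temp_peak_doy) / 365.25)
    run <- contiguous_runs(dates)
    noise <- numeric(n)
    for (r in unique(run)) {
      idx <- which(run == r)
      e <- numeric(length(idx))
      sd0 <- if (config$ar_sd > 0) config$ar_sd / sqrt(1 - config$ar1^2) else 0
      e[1] <- stats::rnorm(1, 0, sd0)
      if (length(idx) > 1L) {
        innov <- stats::rnorm(length(idx) - 1L, 0, config$ar_sd)
        for (t in 2:length(idx)) e[t] <- config$ar1 * e[t - 1L] + innov[t - 1L]
      }
      noise[idx] <- e
    }
    temp <- seasonal + noise
    depression <- stats::rgamma(n, shape = config$dew_shape, scale = config$dew_scale)
    dew <- temp - depression
    wind <- stats::rlnorm(n, config$wind_meanlog, config$wind_sdlog)
    solar <- pmax(5, config$solar_mean +
                    config$solar_amp * cos(2 * pi * (doy - 172) / 365.25) +
                    stats::rnorm(n, 0, config$solar_sd))
    rain <- stats::rbinom(n, 1L, config$rain_prob)
    amount <- stats::rgamma(n, shape = config$rain_shape, scale = config$rain_scale)
    precip <- round(rain * amount, 2)
    data.frame(date = dates, temp_c = temp, dewpoint_c = dew, wind_ms = wind,
               solar_wm2 = solar, precip_mm = precip)
  })
}

# two-day-mean AT used internally by the generator; the first day of each
# contiguous run (no history) falls back to the same-day value
.gen_at2 <- function(weather) {
  at <- apparent_temperature(weather$temp_c, weather$dewpoint_c)
  at2 <- apply_by_run(at, weather$date, lag_mean, lags = 0:1)
  ifelse(is.na(at2), at, at2)
}

#' Generate daily pollutant concentrations with injectable missingness
#'
#' Each pollutant is an intercept plus a linear response to two-day-mean
#' apparent temperature, solar-radiation and wind terms, and Gaussian
#' noise, floored at a small positive value. A fraction `missing_frac` of
#' days per pollutant is masked missing completely at random.
#'
#' @param weather output of [generate_weather()]
#' @param config the same [scenario_config()]
#' @return list with elements `observed` (data frame `date`, `o3_ppb`,
#'   `pm10_ugm3`, `no2_ppb` with `NA` where masked), `complete` (unmasked
#'   values, used for the generator's ground truth) and `mask` (logical
#'   data frame, `TRUE` = masked)
#' @export
generate_pollutants <- function(weather, config) {
  validate_scenario_config(config)
  expected <- scenario_dates(config)
  if (!identical(as.integer(weather$date), as.integer(expected))) {
    stop("alignment error: weather dates do not cover the configured scenario dates")
  }
  n <- nrow(weather)
  at2 <- .gen_at2(weather)
  with_seed(config$seed + 1L, {
    complete <- data.frame(date = weather$date)
    cols <- c(o3 = "o3_ppb", pm10 = "pm10_ugm3", no2 = "no2_ppb")
    for (p in names(cols)) {
      mu <- config$pollutant_intercept[[p]] +
        config$alpha_at_to_pollutant[[p]] * at2 +
        config$pollutant_solar[[p]] * weather$solar_wm2 +
        config$pollutant_wind[[p]] * weather$wind_ms
      complete[[cols[[p]]]] <- pmax(1, mu + stats::rnorm(n, 0, config$pollutant_noise_sd[[p]]))
    }
    mask <- data.frame(date = weather$date)
    observed <- complete
    for (v in cols) {
      m <- stats::runif(n) < config$missing_frac
      mask[[v]] <- m
      observed[[v]][m] <- NA_real_
    }
    list(observed = observed, complete = complete, mask = mask)
  })
}

# Solve the stratum-specific excess log-rate per degree C of hinge that
# attains an additive-interaction target at the p95-vs-p50 contrast.
#
# The downstream interaction model fits stratum COUNTS with no person-time
# offset (no at-risk denominator exists), so the rate ratio it identifies
# for a modifier at reference temperature is share_ratio * exp(delta),
# where share_ratio is the population-share ratio of the modifier's
# stratum to the reference stratum. The calibration therefore targets
#   RERI(eta) = c e^{delta + (beta+eta) d} - e^{beta d} - c e^{delta} + 1
# with c the share ratio, making the generator's truth the estimand the
# fitted model actually recovers.
solve_interaction_slope <- function(target, delta, beta_at, contrast_c,
                                    share_ratio = 1, tol = 1e-8) {
  if (target == 0) return(0)
  c0 <- share_ratio
  rhs <- target + exp(beta_at * contrast_c) + c0 * exp(delta) - 1
  if (rhs <= 0) {
    stop("RERI target ", target, " unattainable: implied RR11 would be <= 0")
  }
  f <- function(eta) {
    c0 * exp(delta + (beta_at + eta) * contrast_c) -
      exp(beta_at * contrast_c) - c0 * exp(delta) + 1 - target
  }
  stats::uniroot(f, lower = -20 / contrast_c, upper = 20 / contrast_c,
                 tol = tol, extendInt = "yes")$root
}

# population-share ratio of each modifier's stratum to the reference
# stratum (all other modifiers absent); the age dummies share the 20-29
# reference category
modifier_share_ratios <- function(prev) {
  p2029 <- 1 - prev["age16_19"] - prev["age30plus"]
  vapply(.modifier_names, function(m) {
    p <- prev[[m]]
    if (p == 0) return(0)
    if (m %in% c("age16_19", "age30plus")) unname(p / p2029) else p / (1 - p)
  }, numeric(1))
}

# enumerate maternal-indicator strata with positive probability; the two
# age indicators never co-occur (three-level age encoded as two dummies)
modifier_strata <- function(prev) {
  grid <- expand.grid(rep(list(0:1), 6L))
  names(grid) <- .modifier_names
  grid <- grid[!(grid$age16_19 == 1 & grid$age30plus == 1), , drop = FALSE]
  p_age <- ifelse(grid$age16_19 == 1, prev["age16_19"],
           ifelse(grid$age30plus == 1, prev["age30plus"],
                  1 - prev["age16_19"] - prev["age30plus"]))
  p <- p_age
  for (m in setdiff(.modifier_names, c("age16_19", "age30plus"))) {
    p <- p * ifelse(grid[[m]] == 1, prev[m], 1 - prev[m])
  }
  grid$prob <- as.numeric(p)
  grid <- grid[grid$prob > 0, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Generate stratified daily preterm-birth counts with known truth
#'
#' For each season day and maternal-indicator stratum, a count is drawn
#' from a Poisson (or negative-binomial when `dispersion > 0`) law whose
#' log mean contains the baseline, a seasonal sinusoid, a piecewise-linear
#' (hinge) effect of two-day-mean apparent temperature above the
#' threshold, pollutant terms evaluated on the unmasked concentrations,
#' modifier main effects and interaction slopes numerically calibrated to
#' the configured additive-interaction targets.
#'
#' @param weather output of [generate_weather()]
#' @param pollutants output of [generate_pollutants()]
#' @param config the same [scenario_config()]
#' @return list: `births` (data frame `date`, six indicator columns,
#'   `count`, season days only) and `truth` (threshold, exposure
#'   percentiles, `beta_at`, true direct/total RR and AF at the
#'   95th-vs-50th percentile contrast, interaction slopes and targets)
#' @export
generate_births <- function(weather, pollutants, config) {
  validate_scenario_config(config)
  if (!identical(as.integer(weather$date), as.integer(pollutants$complete$date))) {
    stop("alignment error: weather and pollutant dates differ")
  }
  doy <- day_of_year(weather$date)
  ref_md <- format(as.Date("2001-01-01") +
                     seq(config$season_days[1], config$season_days[2]) - 1L,
                   "%m-%d")
  season <- format(weather$date, "%m-%d") %in% ref_md
  at2 <- .gen_at2(weather)

  q <- exposure_percentiles(at2[season])
  threshold <- if (is.null(config$at_threshold_c)) unname(q["p50"]) else config$at_threshold_c
  hinge <- pmax(0, at2 - threshold)
  contrast <- max(0, q["p95"] - threshold) - max(0, q["p50"] - threshold)
  if (!is.null(config$beta_at)) {
    beta_at <- config$beta_at
  } else if (config$rr_target == 1) {
    beta_at <- 0
  } else {
    if (contrast <= 0) stop("degenerate exposure contrast; cannot calibrate beta_at")
    beta_at <- log(config$rr_target) / contrast
  }

  delta <- config$modifier_log_rr
  share <- modifier_share_ratios(config$modifier_prevalences)
  eta <- vapply(.modifier_names, function(m) {
    solve_interaction_slope(config$reri_targets[[m]], delta[[m]], beta_at,
                            contrast, share_ratio = share[[m]])
  }, numeric(1))
  reri_implied <- vapply(.modifier_names, function(m) {
    c0 <- share[[m]]
    if (c0 == 0) return(NA_real_)
    c0 * exp(delta[[m]] + (beta_at + eta[[m]]) * contrast) -
      exp(beta_at * contrast) - c0 * exp(delta[[m]]) + 1
  }, numeric(1))

  strata <- modifier_strata(config$modifier_prevalences)
  ind <- as.matrix(strata[, .modifier_names])
  gam <- c(config$gamma_o3, config$gamma_pm10, config$gamma_no2)
  poll <- as.matrix(pollutants$complete[, c("o3_ppb", "pm10_ugm3", "no2_ppb")])
  day_lp <- config$beta0 +
    (config$seasonal_amplitude / 2) *
      cos(2 * pi * (doy - config$rate_peak_doy) / 365.25) +
    beta_at * hinge + as.numeric(poll %*% gam)

  keep <- which(season)
  with_seed(config$seed + 2L, {
    rows <- vector("list", length(keep))
    strat_lp0 <- log(strata$prob) + as.numeric(ind %*% delta)
    strat_slope <- as.numeric(ind %*% eta)
    for (i in seq_along(keep)) {
      d <- keep[i]
      mu <- exp(day_lp[d] + strat_lp0 + strat_slope * hinge[d])
      cnt <- if (config$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
      rows[[i]] <- data.frame(date = weather$date[d], strata[, .modifier_names],
                              count = cnt)
    }
    births <- do.call(rbind, rows)
    rownames(births) <- NULL

    rr_direct <- exp(beta_at * contrast)
    rr_total <- exp(beta_at * contrast +
                      sum(gam * unlist(config$alpha_at_to_pollutant)) *
                        (q["p95"] - q["p50"]))
    truth <- list(
      scenario = config$scenario, seed = config$seed,
      at_threshold_c = threshold,
      at_p50 = unname(q["p50"]), at_p95 = unname(q["p95"]),
      beta_at = beta_at,
      rr_direct = unname(rr_direct), rr_total = unname(rr_total),
      af_direct = unname((1 - 1 / rr_direct) * 100),
      af_total = unname((1 - 1 / rr_total) * 100),
      af_indirect = unname((1 - 1 / rr_total) * 100 - (1 - 1 / rr_direct) * 100),
      interaction_slopes = eta, reri_targets = config$reri_targets,
      reri_implied = reri_implied, modifier_log_rr = delta
    )
    list(births = births, truth = truth)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs [generate_weather()], [generate_pollutants()] and
#' [generate_births()] under one configuration. The three tables share an
#' identical gap-free date index within the season window; the warm-up
#' days preceding the window appear only in the weather and pollutant
#' tables (they exist so the two-day-mean exposure is defined from the
#' first season day).
#'
#' @param config a [scenario_config()]
#' @return list of class `synthetic_dataset`: `weather`, `pollutants`
#'   (observed, with missingness), `pollutants_complete`, `mask`,
#'   `births`, `truth`, `config`
#' @export
simulate_dataset <- function(config) {
  weather <- generate_weather(config)
  poll <- generate_pollutants(weather, config)
  bt <- generate_births(weather, poll, config)
  structure(list(weather = weather, pollutants = poll$observed,
                 pollutants_complete = poll$complete, mask = poll$mask,
                 births = bt$births, truth = bt$truth, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV plus a truth JSON
#'
#' @param dataset a [simulate_dataset()] result
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(dataset$weather, "weather.csv")
  wr(dataset$pollutants, "pollutants.csv")
  wr(dataset$births, "births.csv")
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Aggregate stratified birth counts to daily totals
#'
#' @param births stratified count table (`date`, indicators, `count`)
#' @return data frame `date`, `count`
#' @export
daily_counts <- function(births) {
  agg <- stats::aggregate(count ~ date, data = births, FUN = sum)
  agg[order(agg$date), , drop = FALSE]
}
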