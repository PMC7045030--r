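# Multiple imputation of missing pollutant values by chained equations,
# using lag 0-2 meteorology and pollutants as predictors.
#
# Plain normal-error regression draws are used rather than predictive-mean
# matching: the imputed pollutants are log-transformed and near-Gaussian,
# and the draw model is then exactly the fitted chained regression. A
# `noise_scale` switch exposes the deterministic limit (0 = no residual
# draws, chain iterated to a fixed point).

.impute_vars <- c("at_c", "solar_wm2", "wind_ms", "ln_precip",
                  "o3_ppb", "ln_pm10", "ln_no2")

#' Build the lag 0-2 predictor table for pollutant imputation
#'
#' For each of the seven exposure-side variables (apparent temperature,
#' solar radiation, wind, log precipitation, ozone, log PM10, log NO2),
#' columns at lags 0, 1 and 2 are produced (21 columns). Lags are computed
#' within contiguous date runs; the first two days of each run have missing
#' lagged predictors.
#'
#' @param series a daily series from [prepare_daily_series()]
#' @param vars variables to lag
#' @param lags lag days
#' @return data frame of `length(vars) * length(lags)` predictor columns,
#'   named `<var>_lag<L>`
#' @export
build_impute_predictors <- function(series, vars = .impute_vars, lags = 0:2) {
  miss <- setdiff(vars, names(series))
  if (length(miss)) stop("series missing imputation variables: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (v in vars) {
    for (L in lags) {
      out[[paste0(v, "_lag", L)]] <-
        apply_by_run(series[[v]], series$date, lag_mean, lags = L)
    }
  }
  as.data.frame(out)
}

#' Multiply impute missing pollutant values with chained equations
#'
#' Iterates per-pollutant linear regressions on the lag 0-2 predictor set
#' (each pollutant's own lag-0 column excluded from its model). Missing
#' cells are initialised at the observed mean, `burn_ins` full sweeps are
#' run, and each of the `m` following sweeps is emitted as a completed
#' dataset. Draws add Gaussian residual noise scaled by `noise_scale`;
#' with `noise_scale = 0` the chain is instead iterated to a fixed point
#' (max-change tolerance 1e-10), which makes the imputation an exact
#' deterministic regression prediction. PM10 and NO2 are imputed on the
#' natural-log scale and back-transformed. Non-missing cells are never
#' altered. Deterministic given the seed.
#'
#' @param series daily series with pollutant columns (`o3_ppb`,
#'   `pm10_ugm3`, `no2_ppb`) possibly missing; meteorology must be complete
#' @param m number of imputations (default 3)
#' @param burn_ins full chained sweeps before the first retained draw
#'   (default 2)
#' @param seed integer seed
#' @param noise_scale multiplier on the residual-draw SD (default 1)
#' @param log_scale pollutant columns imputed on the log scale
#' @return object of class `imputation_set`: `completed` (list of m
#'   complete daily series), `m`, `burn_ins`, `seed`, `predictor_spec`,
#'   and `drift` (between-sweep mean absolute change of imputed cells per
#'   variable, an automated stand-in for trace-plot convergence checks)
#' @export
mice_impute <- function(series, m = 3L, burn_ins = 2L, seed = 1L,
                        noise_scale = 1, log_scale = c("pm10_ugm3", "no2_ppb")) {
  targets <- c("o3_ppb", "pm10_ugm3", "no2_ppb")
  miss <- setdiff(targets, names(series))
  if (length(miss)) stop("series missing pollutant columns: ",
                         paste(miss, collapse = ", "))
  met <- c("at_c", "solar_wm2", "wind_ms", "ln_precip")
  if (anyNA(series[met])) {
    stop("missingness must be confined to pollutant columns; meteorology has NA")
  }

  # working copies on the imputation scale
  work <- list()
  na_mask <- list()
  for (t in targets) {
    x <- series[[t]]
    if (all(is.na(x))) stop("impossible imputation: pollutant column '", t,
                            "' is entirely missing")
    na_mask[[t]] <- is.na(x)
    work[[t]] <- if (t %in% log_scale) {
      log_transform_skewed(x, offset = 0, floor = 0.5)
    } else x
    work[[t]][na_mask[[t]]] <- mean(work[[t]], na.rm = TRUE)
  }

  # assemble a working series whose derived log columns track the chain
  current_series <- function() {
    s <- series
    s$o3_ppb <- work[["o3_ppb"]]
    s$ln_pm10 <- if ("pm10_ugm3" %in% log_scale) work[["pm10_ugm3"]] else
      log_transform_skewed(work[["pm10_ugm3"]], 0, 0.5)
    s$ln_no2 <- if ("no2_ppb" %in% log_scale) work[["no2_ppb"]] else
      log_transform_skewed(work[["no2_ppb"]], 0, 0.5)
    s$pm10_ugm3 <- if ("pm10_ugm3" %in% log_scale) exp(work[["pm10_ugm3"]]) else work[["pm10_ugm3"]]
    s$no2_ppb <- if ("no2_ppb" %in% log_scale) exp(work[["no2_ppb"]]) else work[["no2_ppb"]]
    # observed cells are restored bit-for-bit (the log round trip must
    # never alter a non-missing value)
    for (t in targets) {
      obs <- !na_mask[[t]]
      s[[t]][obs] <- series[[t]][obs]
    }
    s
  }
  target_pred_col <- c(o3_ppb = "o3_ppb", pm10_ugm3 = "ln_pm10", no2_ppb = "ln_no2")

  sweep_once <- function(draw) {
    max_change <- stats::setNames(numeric(length(targets)), targets)
    for (t in targets) {
      if (!any(na_mask[[t]])) next
      pred <- build_impute_predictors(current_series())
      pred[[paste0(target_pred_col[[t]], "_lag0")]] <- NULL
      X <- as.matrix(pred)
      # mean-fill run-boundary lag cells so every analysis day is predictable
      for (j in seq_len(ncol(X))) {
        nas <- is.na(X[, j])
        if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
      }
      X <- cbind(`(Intercept)` = 1, X)
      y <- work[[t]]
      obs <- !na_mask[[t]]
      fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      dfres <- sum(obs) - fit$rank
      sigma <- if (dfres > 0) sqrt(sum(fit$residuals^2) / dfres) else 0
      pred_miss <- as.numeric(X[na_mask[[t]], , drop = FALSE] %*% beta)
      if (draw && noise_scale > 0) {
        pred_miss <- pred_miss +
          stats::rnorm(length(pred_miss), 0, sigma * noise_scale)
      }
      max_change[t] <- if (length(pred_miss)) {
        max(abs(pred_miss - y[na_mask[[t]]]))
      } else 0
      work[[t]][na_mask[[t]]] <<- pred_miss
    }
    max_change
  }

  drift <- list()
  completed <- vector("list", m)
  with_seed(seed, {
    for (b in seq_len(burn_ins)) drift[[length(drift) + 1L]] <- sweep_once(draw = TRUE)
    if (noise_scale == 0) {
      # deterministic limit: iterate to the chained-equations fixed point
      for (it in seq_len(50L)) {
        ch <- sweep_once(draw = FALSE)
        drift[[length(drift) + 1L]] <- ch
        if (max(ch) < 1e-10) break
      }
      snap <- current_series()
      for (i in seq_len(m)) completed[[i]] <- snap
    } else {
      for (i in seq_len(m)) {
        drift[[length(drift) + 1L]] <- sweep_once(draw = TRUE)
        completed[[i]] <- current_series()
      }
    }
  })
  drift <- do.call(rbind, drift)
  structure(list(completed = completed, m = as.integer(m),
                 burn_ins = as.integer(burn_ins), seed = as.integer(seed),
                 predictor_spec = list(vars = .impute_vars, lags = 0:2),
                 noise_scale = noise_scale, drift = drift),
            class = "imputation_set")
}
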