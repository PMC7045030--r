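# Natural direct effects via inverse odds weighting: regress the exposure
# on the pollutant mediators plus confounders, convert predictions to
# per-day weights, refit the count model weighted and without pollutants,
# and decompose total = direct + indirect, pooling over imputations.

# lag 0-1 means of the mediators, matching the exposure's two-day window.
# If the columns are already present (e.g. inside a bootstrap resample,
# where the date index is no longer contiguous) they are reused as-is.
.mediator_cols <- c("o3_01", "ln_pm10_01", "ln_no2_01")

.mediator_means <- function(series) {
  if (all(.mediator_cols %in% names(series))) {
    return(series[, .mediator_cols, drop = FALSE])
  }
  lag01 <- function(x) {
    m <- apply_by_run(x, series$date, lag_mean, lags = 0:1)
    ifelse(is.na(m) & !is.na(x), x, m)  # run-boundary days: same-day value
  }
  data.frame(o3_01 = lag01(series$o3_ppb),
             ln_pm10_01 = lag01(series$ln_pm10),
             ln_no2_01 = lag01(series$ln_no2))
}

#' Append lag 0-1 mediator means as columns
#'
#' Adds `o3_01`, `ln_pm10_01`, `ln_no2_01` so later stages (and bootstrap
#' resamples, which break date contiguity) need not recompute lag windows.
#'
#' @param series completed daily series
#' @return the series with the three columns appended
#' @export
add_mediator_means <- function(series) {
  mm <- .mediator_means(series)
  for (v in names(mm)) series[[v]] <- mm[[v]]
  series
}

.confounder_matrix <- function(series, season = NULL) {
  C <- as.matrix(series[, c("solar_wm2", "wind_ms", "ln_precip")])
  if (!is.null(season)) {
    B <- splines::splineDesign(season$knots,
                               pmin(pmax(series$doy, season$boundary[1]),
                                    season$boundary[2]), ord = 4L)[, -1, drop = FALSE]
    colnames(B) <- paste0("doy_bs", seq_len(ncol(B)))
    C <- cbind(C, B)
  }
  C
}

#' Linear exposure model: apparent temperature on mediators and confounders
#'
#' Ordinary least squares regression of the two-day-mean apparent
#' temperature on the lag 0-1 means of the three pollutant mediators
#' (ozone, log PM10, log NO2) and the confounders (solar radiation, wind,
#' log precipitation). `sigma2` is the residual sum of squares over the
#' residual degrees of freedom (the model mean squared error).
#'
#' With `season_knots > 0` a day-of-year cubic b-spline joins the
#' confounder set of both regressions. The default (0) is the regression
#' exactly as printed in the source method; the seasonal extension exists
#' because the density-ratio weight scheme needs the exposure density
#' given confounders to be well specified, and season is the dominant
#' driver of apparent temperature.
#'
#' @param series completed (imputed) daily series; mediator values must be
#'   non-missing on analysis days
#' @param season_knots interior knots of an optional day-of-year spline in
#'   the confounder set (0 = none)
#' @param sigma2_floor guard against a degenerate (near-interpolating) fit
#' @return object of class `exposure_model`: `coefficients`, `sigma2`,
#'   `sigma2_reduced`, `coefficients_reduced` (confounders-only model, used
#'   by the density-ratio weight scheme)
#' @export
fit_exposure_model <- function(series, season_knots = 0L, sigma2_floor = 1e-8) {
  season <- NULL
  if (season_knots > 0L) {
    boundary <- range(series$doy)
    probs <- seq(0, 1, length.out = season_knots + 2L)[-c(1L, season_knots + 2L)]
    interior <- stats::quantile(series$doy, probs = probs, type = 7, names = FALSE)
    season <- list(knots = c(rep(boundary[1], 4L), interior, rep(boundary[2], 4L)),
                   boundary = boundary)
  }
  med <- .mediator_means(series)
  conf <- .confounder_matrix(series, season)
  ok <- stats::complete.cases(med) & stats::complete.cases(conf) &
    !is.na(series$at2_c)
  if (!any(ok)) stop("no complete rows for the exposure model")
  if (anyNA(med)) {
    stop("mediators missing on analysis days; impute before fitting the exposure model")
  }
  y <- series$at2_c[ok]
  Xf <- cbind(`(Intercept)` = 1, as.matrix(med)[ok, , drop = FALSE],
              conf[ok, , drop = FALSE])
  if (qr(Xf)$rank < ncol(Xf)) stop("fit error: collinear mediators/confounders")
  ff <- stats::lm.fit(Xf, y)
  df_f <- length(y) - ff$rank
  s2f <- sum(ff$residuals^2) / df_f
  if (s2f < sigma2_floor) {
    stop("exposure model sigma2 below floor (", sigma2_floor,
         "): mediators interpolate the exposure")
  }
  Xr <- cbind(`(Intercept)` = 1, conf[ok, , drop = FALSE])
  fr <- stats::lm.fit(Xr, y)
  s2r <- sum(fr$residuals^2) / (length(y) - fr$rank)
  structure(list(coefficients = ff$coefficients, sigma2 = s2f,
                 coefficients_reduced = fr$coefficients, sigma2_reduced = s2r,
                 season = season, n = length(y)),
            class = "exposure_model")
}

.predict_exposure <- function(model, series, reduced = FALSE) {
  med <- .mediator_means(series)
  conf <- .confounder_matrix(series, model$season)
  if (reduced) {
    X <- cbind(1, conf)
    as.numeric(X %*% model$coefficients_reduced)
  } else {
    X <- cbind(1, as.matrix(med), conf)
    as.numeric(X %*% model$coefficients)
  }
}

#' Per-day inverse odds weights
#'
#' Two schemes, both computed in log space and normalised to mean one
#' (the weighted Poisson likelihood is invariant to the common scale, and
#' the unnormalised literal values underflow):
#' \describe{
#'   \item{literal_eq1}{`w_d = 1 / exp(Ahat_d / sigma2)` with `Ahat_d` the
#'     exposure-model prediction; the formula as printed in the source
#'     method. It does not involve the observed exposure.}
#'   \item{density_ratio}{`w_d = f(A_d | confounders) / f(A_d | mediators +
#'     confounders)` with normal densities from the two regressions; the
#'     standard inverse-odds construction, under which the
#'     parameter-recovery properties are asserted. When the mediators carry
#'     no information about the exposure the two densities coincide and
#'     all weights are (approximately) one.}
#' }
#'
#' For the density-ratio scheme the log-weights are symmetrically
#' truncated at the `truncate` quantiles before normalisation (standard
#' inverse-probability-weight stabilisation; a handful of days in the far
#' tail of the exposure density otherwise dominate the weighted fit).
#' Truncation does not apply to the literal scheme, which is kept exactly
#' as printed.
#'
#' @param model an [fit_exposure_model()] result (for the density-ratio
#'   scheme, fit with `season_knots > 0` so the exposure density given
#'   confounders is well specified)
#' @param series completed daily series
#' @param scheme weight scheme
#' @param truncate lower/upper quantiles for log-weight truncation
#'   (density-ratio scheme only); `NULL` disables
#' @return positive numeric vector, mean one, with attribute `"scheme"`
#' @export
inverse_odds_weights <- function(model, series,
                                 scheme = c("literal_eq1", "density_ratio"),
                                 truncate = c(0.01, 0.99)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(model, "exposure_model"))
  if (model$sigma2 < 1e-8) stop("sigma2 below positive floor")
  if (scheme == "literal_eq1") {
    pred <- .predict_exposure(model, series)
    logw <- -pred / model$sigma2
  } else {
    pred_f <- .predict_exposure(model, series)
    pred_r <- .predict_exposure(model, series, reduced = TRUE)
    logw <- stats::dnorm(series$at2_c, pred_r, sqrt(model$sigma2_reduced), log = TRUE) -
      stats::dnorm(series$at2_c, pred_f, sqrt(model$sigma2), log = TRUE)
    if (!is.null(truncate)) {
      qq <- stats::quantile(logw, truncate, names = FALSE)
      logw <- pmin(pmax(logw, qq[1]), qq[2])
    }
  }
  if (anyNA(logw)) stop("weights undefined: missing mediator or exposure values")
  w <- normalise_log_weights(logw)
  attr(w, "scheme") <- scheme
  w
}

#' Natural direct effect: inverse-odds-weighted count fit
#'
#' Refits the total-effects design (seasonal and year splines, AT terms,
#' confounders, no pollutants) with the inverse odds weights; the weights
#' render the exposure independent of the mediators, so the weighted AT
#' coefficients estimate the natural direct effect.
#'
#' @param series completed daily series
#' @param counts daily counts aligned with `series`
#' @param weights positive per-day weights from [inverse_odds_weights()]
#' @param spec a [model_spec()]
#' @param contrast `c(at_ref, at_hi)`; default empirical p50/p95
#' @return list: `rr`, `af_percent`, `fit`
#' @export
estimate_direct <- function(series, counts, weights, spec = model_spec(),
                            contrast = NULL) {
  if (length(weights) != nrow(series)) stop("weights misaligned with series")
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(contrast)) {
    q <- exposure_percentiles(series$at2_c)
    contrast <- c(q[["p50"]], q[["p95"]])
  }
  pt <- .point_effect(series, counts, spec, contrast, weights = weights)
  list(rr = pt$rr, af_percent = pt$af, fit = pt$fit)
}

#' Pool per-imputation totals and directs; indirect = total - direct
#'
#' Point estimates are pooled as arithmetic means over imputations; the
#' indirect attributable fraction is exactly the pooled total minus the
#' pooled direct.
#'
#' @param total_afs,direct_afs equal-length numeric vectors, one entry per
#'   imputation
#' @return list: `total_af`, `direct_af`, `indirect_af`, `m_pooled`
#' @export
decompose_and_pool <- function(total_afs, direct_afs) {
  if (length(total_afs) != length(direct_afs)) {
    stop("pooling error: mismatched imputation counts (",
         length(total_afs), " vs ", length(direct_afs), ")")
  }
  total <- mean(total_afs)
  direct <- mean(direct_afs)
  list(total_af = total, direct_af = direct,
       indirect_af = total - direct, m_pooled = length(total_afs))
}

#' Mediation analysis: total, direct and indirect attributable fractions
#'
#' For each completed dataset, fits the total-effect model, the exposure
#' model and the inverse-odds-weighted direct-effect model; pools over
#' imputations; and bootstraps the whole two-stage procedure (exposure
#' model, weights and weighted fit are re-estimated inside every
#' resample, so the interval reflects weight-estimation uncertainty).
#' Resampled day indices are shared across imputations within a resample.
#'
#' @param completed a list of completed daily series (e.g.
#'   `mice_impute(...)$completed`), or a single series
#' @param counts daily counts aligned with the series
#' @param spec a [model_spec()]
#' @param scheme weight scheme, see [inverse_odds_weights()]
#' @param n_boot bootstrap resamples (default 500); 0 = point estimates only
#' @param seed integer seed
#' @param contrast optional `c(at_ref, at_hi)`
#' @return object of class `mediation_result`: pooled `total_af`,
#'   `direct_af`, `indirect_af`, `rr_total`, `rr_direct`, percentile `cis`,
#'   `m_pooled`, `weight_scheme`
#' @export
mediate <- function(completed, counts, spec = model_spec(),
                    scheme = c("literal_eq1", "density_ratio"),
                    n_boot = 500L, seed = 1L, contrast = NULL) {
  scheme <- match.arg(scheme)
  if (is.data.frame(completed)) completed <- list(completed)
  completed <- lapply(completed, add_mediator_means)
  if (is.null(contrast)) {
    q <- exposure_percentiles(completed[[1]]$at2_c)
    contrast <- c(q[["p50"]], q[["p95"]])
  }
  season_knots <- if (scheme == "density_ratio") 4L else 0L
  one_pass <- function(series_list, cnt, spec_use) {
    tot <- dir <- rr_t <- rr_d <- numeric(length(series_list))
    for (i in seq_along(series_list)) {
      s <- series_list[[i]]
      te <- .point_effect(s, cnt, spec_use, contrast)
      em <- fit_exposure_model(s, season_knots = season_knots)
      w <- inverse_odds_weights(em, s, scheme)
      de <- estimate_direct(s, cnt, w, spec_use, contrast)
      tot[i] <- te$af; dir[i] <- de$af_percent
      rr_t[i] <- te$rr; rr_d[i] <- de$rr
    }
    c(total = mean(tot), direct = mean(dir), indirect = mean(tot) - mean(dir),
      rr_total = mean(rr_t), rr_direct = mean(rr_d))
  }
  pt <- one_pass(completed, counts, spec)
  # freeze the hinge at the full-data location across resamples
  spec_fixed <- spec
  if (is.null(spec_fixed$at_knot_c)) {
    spec_fixed$at_knot_c <- build_design(completed[[1]], spec)$at_knot
  }
  boot <- NULL
  n_failed <- 0L
  if (n_boot > 0L) {
    n <- nrow(completed[[1]])
    boot <- matrix(NA_real_, n_boot, 3L,
                   dimnames = list(NULL, c("total", "direct", "indirect")))
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(
          one_pass(lapply(completed, function(s) s[idx, , drop = FALSE]),
                   counts[idx], spec_fixed),
          error = function(e) NULL)
        if (is.null(res)) n_failed <- n_failed + 1L else boot[b, ] <- res[1:3]
      }
    })
    if (n_failed > 0.05 * n_boot) {
      stop("bootstrap error: ", n_failed, " of ", n_boot, " resamples failed")
    }
  }
  ci <- function(j) if (is.null(boot)) c(NA_real_, NA_real_) else {
    stats::quantile(boot[, j], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  structure(list(total_af = unname(pt["total"]), direct_af = unname(pt["direct"]),
                 indirect_af = unname(pt["indirect"]),
                 rr_total = unname(pt["rr_total"]), rr_direct = unname(pt["rr_direct"]),
                 cis = list(total = ci("total"), direct = ci("direct"),
                            indirect = ci("indirect")),
                 m_pooled = length(completed), weight_scheme = scheme,
                 at_ref_c = contrast[1], at_hi_c = contrast[2],
                 n_boot = as.integer(n_boot), n_failed = n_failed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(v, ci) {
    s <- sprintf("%.1f%%", v)
    if (!is.na(ci[1])) s <- paste0(s, sprintf(" (95%% CI %.1f to %.1f)", ci[1], ci[2]))
    s
  }
  cat("Attributable fractions at", sprintf("%.1f vs %.1f C", x$at_hi_c, x$at_ref_c),
      "— scheme:", x$weight_scheme, "\n")
  cat("  total:   ", fmt(x$total_af, x$cis$total), "\n")
  cat("  direct:  ", fmt(x$direct_af, x$cis$direct), "\n")
  cat("  indirect:", fmt(x$indirect_af, x$cis$indirect), "\n")
  invisible(x)
}
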