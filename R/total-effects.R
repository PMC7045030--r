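# Total effects: spline Poisson time-series model of daily preterm-birth
# counts on two-day-mean apparent temperature, with relative risks,
# attributable fractions and bootstrap percentile intervals.

#' Model specification for the count time-series models
#'
#' @param doy_knots interior-knot count of the day-of-year cubic b-spline
#'   (2, 5 or 8 in replication mode; any positive integer accepted)
#' @param year_knots interior-knot count of the year cubic b-spline
#'   (default 2); when the study has too few distinct years for the basis,
#'   year indicator dummies are substituted
#' @param at_knot_c hinge location of the piecewise-linear apparent
#'   temperature term; `NULL` (default) places it at the empirical median
#' @param covariates confounder subset, any of `"solar"`, `"wind"`,
#'   `"ln_precip"`
#' @param family `"poisson"` or `"negative_binomial"`
#' @return object of class `model_spec`
#' @export
model_spec <- function(doy_knots = 5L, year_knots = 2L, at_knot_c = NULL,
                       covariates = c("solar", "wind", "ln_precip"),
                       family = c("poisson", "negative_binomial")) {
  family <- match.arg(family)
  if (doy_knots < 1L) stop("doy_knots must be a positive integer")
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("solar", "wind", "ln_precip"),
                            several.ok = TRUE)
  } else {
    covariates <- character(0)  # crude model: splines and AT terms only
  }
  structure(list(doy_knots = as.integer(doy_knots),
                 year_knots = as.integer(year_knots),
                 at_knot_c = at_knot_c, covariates = covariates,
                 family = family),
            class = "model_spec")
}

#' Cubic b-spline basis with interior knots at equally spaced quantiles
#'
#' Full (unpenalised) basis including all functions, so rows sum to one
#' (partition of unity); drop a column before combining with an intercept.
#' Basis dimension is `n_interior + degree + 1`.
#'
#' @param x numeric vector
#' @param n_interior interior knot count
#' @param degree spline degree (default cubic)
#' @param boundary boundary knots (default data range)
#' @return matrix with `length(x)` rows
#' @export
bspline_basis <- function(x, n_interior, degree = 3L, boundary = range(x)) {
  probs <- seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  interior <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
  knots <- c(rep(boundary[1], degree + 1L), interior, rep(boundary[2], degree + 1L))
  splines::splineDesign(knots, pmin(pmax(x, boundary[1]), boundary[2]),
                        ord = degree + 1L)
}

.covariate_cols <- c(solar = "solar_wm2", wind = "wind_ms",
                     ln_precip = "ln_precip")

#' Build the regression design matrix
#'
#' Columns: intercept, day-of-year cubic b-spline basis, year cubic
#' b-spline basis (or year dummies when years are too few for the basis),
#' a linear apparent-temperature term, the hinge term
#' `max(0, AT2 - at_knot_c)`, and the requested confounders. The column
#' map names every term group.
#'
#' @param series daily series (complete on analysis days)
#' @param spec a [model_spec()]
#' @return list: `X` (design matrix), `map` (column indices by group),
#'   `at_knot` (resolved hinge location), `at_range` (observed exposure
#'   range)
#' @export
build_design <- function(series, spec) {
  at <- series$at2_c
  if (anyNA(at)) stop("design error: missing at2_c on analysis days")
  at_knot <- if (is.null(spec$at_knot_c)) {
    unname(stats::quantile(at, 0.5, type = 7))
  } else spec$at_knot_c
  if (at_knot <= min(at) || at_knot >= max(at)) {
    stop("design error: at_knot_c must lie strictly inside the observed AT range")
  }
  doyB <- bspline_basis(series$doy, spec$doy_knots)[, -1, drop = FALSE]
  colnames(doyB) <- paste0("doy_bs", seq_len(ncol(doyB)))
  yix <- series$year - min(series$year) + 1L
  nyr <- length(unique(yix))
  if (nyr == 1L) {
    yearB <- NULL
  } else if (nyr > spec$year_knots + 4L) {
    yearB <- bspline_basis(yix, spec$year_knots)[, -1, drop = FALSE]
    colnames(yearB) <- paste0("year_bs", seq_len(ncol(yearB)))
  } else {
    # too few distinct years for a cubic basis: indicator dummies
    yearB <- stats::model.matrix(~ factor(yix))[, -1, drop = FALSE]
    colnames(yearB) <- paste0("year_f", sort(unique(yix))[-1])
  }
  covs <- NULL
  if (length(spec$covariates)) {
    cc <- .covariate_cols[spec$covariates]
    miss <- setdiff(unname(cc), names(series))
    if (length(miss)) stop("design error: series missing covariate columns: ",
                           paste(miss, collapse = ", "))
    covs <- as.matrix(series[, unname(cc), drop = FALSE])
    if (anyNA(covs)) stop("design error: missing covariate values on analysis days")
  }
  X <- cbind(`(Intercept)` = 1, doyB, yearB,
             at_lin = at, at_hinge = pmax(0, at - at_knot), covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design error: rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  grp <- function(nm) which(colnames(X) %in% nm)
  list(X = X,
       map = list(intercept = 1L, doy = grp(colnames(doyB)),
                  year = if (is.null(yearB)) integer(0) else grp(colnames(yearB)),
                  at_lin = grp("at_lin"), at_hinge = grp("at_hinge"),
                  covariates = if (is.null(covs)) integer(0) else grp(colnames(covs))),
       at_knot = at_knot, at_range = range(at))
}

#' Fit the count regression
#'
#' Maximum-likelihood Poisson (via iteratively reweighted least squares)
#' or negative-binomial (via [MASS::glm.nb()]) fit of daily counts on a
#' design from [build_design()]. Supports per-observation weights, which
#' the mediation module uses for inverse-odds-weighted fits; weights enter
#' the likelihood multiplicatively, so rescaling all weights by a positive
#' constant leaves the coefficients unchanged.
#'
#' @param counts non-negative integer counts aligned to design rows
#' @param design output of [build_design()]
#' @param spec the [model_spec()] (family)
#' @param weights optional positive per-day weights
#' @return object of class `count_fit`: `coefficients`, `vcov`, `map`,
#'   `at_knot`, `at_range`, `deviance`, `theta` (NB only), `dispersion`
#'   (Pearson statistic / df), `converged`, `family`
#' @export
fit_count_model <- function(counts, design, spec = model_spec(),
                            weights = NULL) {
  X <- design$X
  if (length(counts) != nrow(X)) stop("counts and design rows differ")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (any(weights <= 0)) stop("weights must be positive")
  theta <- NA_real_
  if (spec$family == "negative_binomial") {
    dat <- data.frame(.y = counts, X[, -1, drop = FALSE], check.names = FALSE)
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(.y ~ ., data = dat, weights = weights)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$theta > 1e5) {
      # dispersion at (or past) the Poisson boundary: fall back, log it
      fit <- stats::glm.fit(X, counts, weights = weights,
                            family = stats::poisson())
      message("negative-binomial dispersion at boundary; falling back to Poisson")
      coefs <- fit$coefficients
      Rmat <- qr.R(fit$qr)
      vc <- chol2inv(Rmat)
      dimnames(vc) <- list(colnames(X)[fit$qr$pivot], colnames(X)[fit$qr$pivot])
      vc <- vc[colnames(X), colnames(X)]
      theta <- Inf
    } else {
      coefs <- stats::setNames(stats::coef(fit), colnames(X))
      vc <- stats::vcov(fit)
      dimnames(vc) <- list(colnames(X), colnames(X))
      theta <- fit$theta
    }
  } else {
    fit <- stats::glm.fit(X, counts, weights = weights,
                          family = stats::poisson())
    if (!fit$converged) stop("fit error: Poisson IRLS did not converge after ",
                             fit$iter, " iterations")
    coefs <- fit$coefficients
    vc <- chol2inv(qr.R(fit$qr))
    dimnames(vc) <- list(colnames(X)[fit$qr$pivot], colnames(X)[fit$qr$pivot])
    vc <- vc[colnames(X), colnames(X)]
  }
  mu <- as.numeric(exp(X %*% coefs))
  pearson <- sum(weights * (counts - mu)^2 / mu) / (nrow(X) - ncol(X))
  structure(list(coefficients = coefs, vcov = vc, map = design$map,
                 at_knot = design$at_knot, at_range = design$at_range,
                 deviance = if (is.list(fit)) fit$deviance else NA_real_,
                 theta = theta, dispersion = pearson,
                 converged = TRUE, family = spec$family),
            class = "count_fit")
}

#' Relative risk at an apparent-temperature contrast
#'
#' Exponentiated difference of the AT-term linear predictor between
#' `at_hi_c` and `at_ref_c`, all other columns held fixed:
#' `exp(b_lin (hi - ref) + b_hinge (h(hi) - h(ref)))` with
#' `h(a) = max(0, a - knot)`.
#'
#' @param fit a [fit_count_model()] result
#' @param at_hi_c,at_ref_c contrast temperatures, degrees C
#' @return scalar relative risk
#' @export
relative_risk <- function(fit, at_hi_c, at_ref_c) {
  stopifnot(inherits(fit, "count_fit"))
  if (at_hi_c < fit$at_range[1] || at_hi_c > fit$at_range[2] ||
      at_ref_c < fit$at_range[1] || at_ref_c > fit$at_range[2]) {
    warning("relative risk requested outside the observed AT range (",
            round(fit$at_range[1], 1), ", ", round(fit$at_range[2], 1), ")")
  }
  b <- fit$coefficients
  h <- function(a) max(0, a - fit$at_knot)
  unname(exp(b["at_lin"] * (at_hi_c - at_ref_c) +
               b["at_hinge"] * (h(at_hi_c) - h(at_ref_c))))
}

#' Attributable fraction from a relative risk
#'
#' The share of cases among the exposed attributable to the exposure,
#' `(1 - 1/RR) * 100` percent. The formula as sometimes printed,
#' `1/(1 - RR) * 100`, is negative for any RR above 1 and is provided
#' behind `literal = TRUE` for documentation only.
#'
#' @param rr positive relative risk
#' @param literal use the literal `1/(1 - RR)` form
#' @return attributable fraction, percent
#' @examples
#' attributable_fraction(1.11) # 9.9 to one decimal
#' @export
attributable_fraction <- function(rr, literal = FALSE) {
  if (any(rr <= 0)) stop("domain error: relative risk must be positive")
  if (literal) return(1 / (1 - rr) * 100)
  (1 - 1 / rr) * 100
}

# internal: one total-effect estimate on a prepared series
.point_effect <- function(series, counts, spec, contrast, weights = NULL) {
  design <- build_design(series, spec)
  fit <- fit_count_model(counts, design, spec, weights = weights)
  rr <- relative_risk(fit, contrast[2], contrast[1])
  list(fit = fit, rr = rr, af = attributable_fraction(rr))
}

#' Total-effect estimate with day-resampling bootstrap CI
#'
#' Fits the spline count model, forms the relative risk and attributable
#' fraction at the p95-vs-p50 contrast of the observed two-day-mean
#' apparent temperature, and builds percentile confidence intervals by
#' resampling days with replacement (`n_boot` resamples; i.i.d. by
#' default, moving blocks of `block` days optionally, for autocorrelation
#' sensitivity). The contrast temperatures and the hinge location are held
#' at their full-data values across resamples. Resamples whose fit fails
#' are skipped and counted; more than 5 percent failures is an error.
#'
#' @param series daily analysis series (complete covariates)
#' @param counts daily counts aligned with `series`
#' @param spec a [model_spec()]
#' @param n_boot bootstrap resamples (default 500); 0 = point estimate only
#' @param seed integer seed
#' @param contrast optional `c(at_ref, at_hi)`; default the empirical
#'   p50/p95 of `series$at2_c`
#' @param block optional moving-block length (days)
#' @return object of class `effect_estimate`: `rr`, `af_percent`,
#'   `ci_rr`, `ci_af`, `at_hi_c`, `at_ref_c`, `n_boot`, `n_failed`, `fit`
#' @export
bootstrap_effect <- function(series, counts, spec = model_spec(),
                             n_boot = 500L, seed = 1L, contrast = NULL,
                             block = NULL) {
  if (is.null(contrast)) {
    q <- exposure_percentiles(series$at2_c)
    contrast <- c(q[["p50"]], q[["p95"]])
  }
  pt <- .point_effect(series, counts, spec, contrast)
  spec_fixed <- spec
  spec_fixed$at_knot_c <- pt$fit$at_knot
  n <- nrow(series)
  boot_rr <- boot_af <- rep(NA_real_, n_boot)
  n_failed <- 0L
  if (n_boot > 0L) {
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- if (is.null(block)) {
          sample.int(n, n, replace = TRUE)
        } else {
          starts <- sample.int(n, ceiling(n / block), replace = TRUE)
          idx0 <- as.vector(outer(0:(block - 1L), starts, "+"))
          ((idx0 - 1L) %% n) + 1L
        }
        res <- tryCatch(
          .point_effect(series[idx, , drop = FALSE], counts[idx],
                        spec_fixed, contrast),
          error = function(e) NULL)
        if (is.null(res)) n_failed <- n_failed + 1L else {
          boot_rr[b] <- res$rr
          boot_af[b] <- res$af
        }
      }
    })
    if (n_failed > 0.05 * n_boot) {
      stop("bootstrap error: ", n_failed, " of ", n_boot, " resamples failed")
    }
  }
  ci <- function(x) if (n_boot > 0L) {
    stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(rr = pt$rr, af_percent = pt$af,
                 ci_rr = ci(boot_rr), ci_af = ci(boot_af),
                 at_hi_c = contrast[2], at_ref_c = contrast[1],
                 n_boot = as.integer(n_boot), n_failed = n_failed,
                 boot_af = boot_af, boot_rr = boot_rr, fit = pt$fit),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("RR at %.1f vs %.1f C: %.3f", x$at_hi_c, x$at_ref_c, x$rr))
  if (x$n_boot > 0L) cat(sprintf(" (95%% CI %.3f to %.3f)", x$ci_rr[1], x$ci_rr[2]))
  cat(sprintf("\nAttributable fraction: %.1f%%", x$af_percent))
  if (x$n_boot > 0L) cat(sprintf(" (95%% CI %.1f to %.1f)", x$ci_af[1], x$ci_af[2]))
  cat("\n")
  invisible(x)
}

#' Exposure-response table over an apparent-temperature grid
#'
#' Relative risk relative to the reference temperature across a grid of
#' the observed exposure range, from the fitted piecewise-linear model;
#' stands in for a plotted exposure-response curve.
#'
#' @param fit a [fit_count_model()] result
#' @param at_ref_c reference temperature (default the hinge)
#' @param n grid size
#' @return data frame `at_c`, `rr`
#' @export
exposure_response_table <- function(fit, at_ref_c = fit$at_knot, n = 50L) {
  grid <- seq(fit$at_range[1], fit$at_range[2], length.out = n)
  data.frame(at_c = grid,
             rr = vapply(grid, relative_risk, numeric(1), fit = fit,
                         at_ref_c = at_ref_c))
}
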