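# Additive effect modification: relative excess risk due to interaction
# (RERI) from a negative-binomial model on stratum-expanded daily counts
# with apparent-temperature-by-modifier interaction terms.

#' Expand birth data to date-by-stratum counts
#'
#' One row per date and realized maternal-indicator combination, with
#' zero-count rows materialised for every (date, realized combination)
#' pair, since most stratum-days have no preterm birth. Input may be
#' per-birth records (no `count` column; each row one birth) or
#' pre-aggregated counts. Contradictory age indicators (both 16-19 and
#' 30-plus set) are a validation error.
#'
#' @param births data frame with `date`, the six indicator columns
#'   (`black`, `age16_19`, `age30plus`, `low_prenatal`, `smoker`,
#'   `no_hs`), and optionally `count`
#' @return data frame `date`, indicators, `count`, sorted by date then
#'   stratum
#' @export
expand_strata <- function(births) {
  need <- c("date", .modifier_names)
  miss <- setdiff(need, names(births))
  if (length(miss)) stop("births table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(births$age16_19 == 1 & births$age30plus == 1)) {
    stop("validation error: age16_19 and age30plus both set on some rows")
  }
  if (!"count" %in% names(births)) births$count <- 1L
  key <- do.call(paste, c(births[.modifier_names], sep = ""))
  combos <- unique(births[order(key), .modifier_names, drop = FALSE])
  rownames(combos) <- NULL
  dates <- sort(unique(births$date))
  grid <- combos[rep(seq_len(nrow(combos)), times = length(dates)), , drop = FALSE]
  grid <- cbind(date = rep(dates, each = nrow(combos)), grid)
  gkey <- paste(grid$date, do.call(paste, c(grid[.modifier_names], sep = "")))
  agg <- stats::aggregate(births$count,
                          by = c(list(date = births$date), births[.modifier_names]),
                          FUN = sum)
  akey <- paste(agg$date, do.call(paste, c(agg[.modifier_names], sep = "")))
  grid$count <- 0L
  grid$count[match(akey, gkey)] <- as.integer(agg$x)
  rownames(grid) <- NULL
  grid
}

#' Fit the interaction model on stratum-expanded counts
#'
#' Negative-binomial (dispersion estimated by maximum likelihood) fit of
#' stratum-day counts with: shared seasonal and year splines, the
#' piecewise-linear apparent-temperature terms, each modifier's main
#' effect, and each modifier's interaction with both the linear and the
#' hinge AT terms. Falls back to Poisson with a logged message when the
#' estimated dispersion sits at the Poisson boundary.
#'
#' @param strata output of [expand_strata()]
#' @param series daily exposure series covering the strata dates
#' @param spec a [model_spec()] (the family field is ignored; the model is
#'   negative binomial by construction)
#' @param modifiers which indicators to model (default all six present
#'   with variation)
#' @param init_theta optional starting value for the NB dispersion
#'   (speeds up bootstrap refits)
#' @return object of class `interaction_fit`: `coefficients`, `vcov`,
#'   `at_knot`, `at_range`, `theta`, `modifiers`, `family`
#' @export
fit_interaction_model <- function(strata, series, spec = model_spec(),
                                  modifiers = NULL, init_theta = NULL) {
  idx <- match(strata$date, series$date)
  if (anyNA(idx)) stop("alignment error: strata dates missing from exposure series")
  if (is.null(modifiers)) {
    modifiers <- .modifier_names[vapply(.modifier_names, function(m) {
      length(unique(strata[[m]])) > 1L
    }, logical(1))]
  }
  day <- series[idx, , drop = FALSE]
  base <- build_design(day, spec)
  X <- base$X
  at <- day$at2_c
  hinge <- pmax(0, at - base$at_knot)
  for (m in modifiers) {
    em <- strata[[m]]
    Xm <- cbind(em, em * at, em * hinge)
    colnames(Xm) <- paste0(m, c("", "_x_at", "_x_hinge"))
    X <- cbind(X, Xm)
  }
  if (qr(X)$rank < ncol(X)) stop("design error: rank-deficient interaction design")
  dat <- data.frame(.y = strata$count, X[, -1, drop = FALSE], check.names = FALSE)
  fit <- tryCatch(
    suppressWarnings(if (is.null(init_theta)) {
      MASS::glm.nb(.y ~ ., data = dat)
    } else {
      MASS::glm.nb(.y ~ ., data = dat, init.theta = init_theta)
    }),
    error = function(e) NULL)
  family <- "negative_binomial"
  if (is.null(fit) || !fit$converged || fit$theta > 1e5) {
    message("negative-binomial dispersion at boundary; falling back to Poisson")
    pf <- stats::glm.fit(X, strata$count, family = stats::poisson())
    if (!pf$converged) stop("fit error: interaction model did not converge")
    coefs <- pf$coefficients
    vc <- chol2inv(qr.R(pf$qr))
    dimnames(vc) <- list(colnames(X)[pf$qr$pivot], colnames(X)[pf$qr$pivot])
    vc <- vc[colnames(X), colnames(X)]
    theta <- Inf
    family <- "poisson"
  } else {
    coefs <- stats::setNames(stats::coef(fit), colnames(X))
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(colnames(X), colnames(X))
    theta <- fit$theta
  }
  structure(list(coefficients = coefs, vcov = vc, at_knot = base$at_knot,
                 at_range = base$at_range, theta = theta,
                 modifiers = modifiers, family = family),
            class = "interaction_fit")
}

#' RERI from three relative risks
#'
#' The additive-interaction statistic `RR11 - RR10 - RR01 + 1`; zero under
#' exact additivity of excess risks.
#'
#' @param rr11 RR at (high exposure, modifier present)
#' @param rr10 RR at (high exposure, modifier absent)
#' @param rr01 RR at (reference exposure, modifier present)
#' @return scalar RERI
#' @examples
#' reri_from_rr(2.0, 1.5, 1.2) # 0.3
#' @export
reri_from_rr <- function(rr11, rr10, rr01) rr11 - rr10 - rr01 + 1

# linear predictor of the AT and modifier terms at (at, em),
# all other modifiers and shared terms at zero
.interaction_lp <- function(fit, modifier, at, em) {
  b <- fit$coefficients
  h <- max(0, at - fit$at_knot)
  lp <- b[["at_lin"]] * at + b[["at_hinge"]] * h
  if (em == 1) {
    lp <- lp + b[[modifier]] + b[[paste0(modifier, "_x_at")]] * at +
      b[[paste0(modifier, "_x_hinge")]] * h
  }
  lp
}

#' Relative excess risk due to interaction for one modifier
#'
#' Builds the three relative risks against the common denominator — the
#' risk at the reference temperature with the modifier (and all other
#' modifiers) absent — from the fitted linear predictor, and returns
#' `RR11 - RR10 - RR01 + 1`.
#'
#' @param fit an [fit_interaction_model()] result
#' @param modifier indicator name
#' @param at_hi_c,at_ref_c contrast temperatures, degrees C
#' @return list of class `reri_result`: `modifier`, `reri`, `rr11`,
#'   `rr10`, `rr01`, `contrast`
#' @export
compute_reri <- function(fit, modifier, at_hi_c, at_ref_c) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (!modifier %in% fit$modifiers) {
    stop("contract error: modifier '", modifier, "' absent from the fit")
  }
  lp0 <- .interaction_lp(fit, modifier, at_ref_c, 0)
  rr11 <- exp(.interaction_lp(fit, modifier, at_hi_c, 1) - lp0)
  rr10 <- exp(.interaction_lp(fit, modifier, at_hi_c, 0) - lp0)
  rr01 <- exp(.interaction_lp(fit, modifier, at_ref_c, 1) - lp0)
  structure(list(modifier = modifier,
                 reri = reri_from_rr(rr11, rr10, rr01),
                 rr11 = rr11, rr10 = rr10, rr01 = rr01,
                 contrast = c(at_ref_c = at_ref_c, at_hi_c = at_hi_c)),
            class = "reri_result")
}

#' Bootstrap CIs for all modifiers' RERIs
#'
#' Cluster bootstrap with the date as the resampling unit: all strata of a
#' resampled date move together (strata within a date share exposure), so
#' within-date stratum sums are preserved in every resample. Refits the
#' interaction model and recomputes every modifier's RERI per resample;
#' percentile intervals.
#'
#' @param strata output of [expand_strata()]
#' @param series daily exposure series
#' @param spec a [model_spec()]
#' @param n_boot resamples (default 1000)
#' @param seed integer seed
#' @param contrast optional `c(at_ref, at_hi)`; default empirical p50/p95
#'   of the analysis-day exposure
#' @param modifiers indicators to report (default: those in the point fit)
#' @return data frame of class `reri_table`: `modifier`, `reri`,
#'   `ci_lower`, `ci_upper`
#' @export
bootstrap_reri <- function(strata, series, spec = model_spec(),
                           n_boot = 1000L, seed = 1L, contrast = NULL,
                           modifiers = NULL) {
  dates <- sort(unique(strata$date))
  if (is.null(contrast)) {
    q <- exposure_percentiles(series$at2_c[series$date %in% dates])
    contrast <- c(q[["p50"]], q[["p95"]])
  }
  fit <- fit_interaction_model(strata, series, spec, modifiers)
  modifiers <- fit$modifiers
  spec_fixed <- spec
  spec_fixed$at_knot_c <- fit$at_knot
  point <- vapply(modifiers, function(m) {
    compute_reri(fit, m, contrast[2], contrast[1])$reri
  }, numeric(1))
  boot <- matrix(NA_real_, n_boot, length(modifiers),
                 dimnames = list(NULL, modifiers))
  n_failed <- 0L
  if (n_boot > 0L) {
    by_date <- split(seq_len(nrow(strata)), match(strata$date, dates))
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        pick <- sample.int(length(dates), length(dates), replace = TRUE)
        idx <- unlist(by_date[pick], use.names = FALSE)
        res <- tryCatch({
          f <- suppressMessages(
            fit_interaction_model(strata[idx, , drop = FALSE], series,
                                  spec_fixed, modifiers,
                                  init_theta = if (is.finite(fit$theta)) fit$theta))
          vapply(modifiers, function(m) {
            compute_reri(f, m, contrast[2], contrast[1])$reri
          }, numeric(1))
        }, error = function(e) NULL)
        if (is.null(res)) n_failed <- n_failed + 1L else boot[b, ] <- res
      }
    })
    if (n_failed > 0.05 * n_boot) {
      stop("bootstrap error: ", n_failed, " of ", n_boot, " resamples failed")
    }
  }
  out <- data.frame(
    modifier = modifiers,
    reri = unname(point),
    ci_lower = apply(boot, 2, function(x) {
      if (all(is.na(x))) NA_real_ else stats::quantile(x, 0.025, na.rm = TRUE, names = FALSE)
    }),
    ci_upper = apply(boot, 2, function(x) {
      if (all(is.na(x))) NA_real_ else stats::quantile(x, 0.975, na.rm = TRUE, names = FALSE)
    }),
    row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  class(out) <- c("reri_table", class(out))
  out
}
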