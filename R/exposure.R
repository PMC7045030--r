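# Exposure preparation: apparent temperature, station backfill, lag means,
# log transforms, warm-season restriction and exposure percentiles.

#' Apparent temperature from air temperature and dew point
#'
#' Humidity-adjusted thermal-discomfort metric
#' \deqn{AT = -2.653 + 0.994\,T + 0.0153\,T_d^2}
#' with \eqn{T} the air temperature and \eqn{T_d} the dew point, both in
#' degrees Celsius. AT is affine in \eqn{T} at fixed dew point
#' (slope 0.994) and monotone non-decreasing in \eqn{T_d} for
#' \eqn{T_d \ge 0}. Negative dew points are legal inputs; the quadratic
#' term uses the signed value squared.
#'
#' @param temp_c air temperature, degrees C
#' @param dewpoint_c dew point temperature, degrees C
#' @return apparent temperature, degrees C; `NA` where either input is
#'   non-finite
#' @examples
#' apparent_temperature(0, 0)    # -2.653
#' apparent_temperature(30, 20)  # 33.287
#' @export
apparent_temperature <- function(temp_c, dewpoint_c) {
  if (length(temp_c) != length(dewpoint_c)) {
    stop("temp_c and dewpoint_c must have the same length")
  }
  at <- -2.653 + 0.994 * temp_c + 0.0153 * dewpoint_c^2
  at[!is.finite(temp_c) | !is.finite(dewpoint_c)] <- NA_real_
  at
}

#' Backfill a primary station's series from a secondary station
#'
#' Values from the primary station are kept wherever present; days missing
#' at the primary are filled from the secondary; days missing at both stay
#' missing (legal, counted). A per-day provenance flag is recorded for every
#' filled column.
#'
#' @param primary data frame with a `date` column plus value columns
#' @param secondary data frame with a `date` column plus (a subset of) the
#'   same value columns
#' @param value_cols columns to fill; defaults to all shared non-date columns
#' @return data frame over the union of dates with each value column plus a
#'   `<col>_src` provenance column (`"primary"`, `"secondary"` or `NA`).
#'   The count of days missing at both stations is attached as attribute
#'   `"missing_both"` (named by column).
#' @export
backfill_station <- function(primary, secondary,
                             value_cols = setdiff(
                               intersect(names(primary), names(secondary)),
                               "date")) {
  stopifnot("date" %in% names(primary), "date" %in% names(secondary))
  if (length(value_cols) == 0L) stop("no shared value columns to backfill")
  dates <- sort(unique(c(primary$date, secondary$date)))
  out <- data.frame(date = dates)
  miss_both <- integer(0)
  for (v in value_cols) {
    p <- primary[[v]][match(dates, primary$date)]
    s <- secondary[[v]][match(dates, secondary$date)]
    out[[v]] <- ifelse(is.na(p), s, p)
    out[[paste0(v, "_src")]] <- ifelse(!is.na(p), "primary",
                                ifelse(!is.na(s), "secondary", NA_character_))
    miss_both[v] <- sum(is.na(p) & is.na(s))
  }
  attr(out, "missing_both") <- miss_both
  out
}

#' Mean of a series over a set of backward lags
#'
#' Maps day \eqn{d} to the mean of the series over days \eqn{d - L} for
#' each lag \eqn{L} in `lags`. Days without the full lag history (the first
#' `max(lags)` days) are missing. The default `lags = 0:1` produces the
#' two-day mean exposure: the value on the day of and the day before birth.
#'
#' @param x numeric series ordered by day
#' @param lags non-negative integer lags; `lags = 0` is the identity
#' @param dates optional `Date` vector; if given it must be strictly
#'   increasing and gap-free, otherwise an input error is raised
#' @return numeric vector the length of `x`
#' @export
lag_mean <- function(x, lags = 0:1, dates = NULL) {
  lags <- as.integer(lags)
  if (any(lags < 0L)) stop("lags must be non-negative")
  if (!is.null(dates)) {
    if (length(dates) != length(x)) stop("dates must match x in length")
    d <- as.integer(dates)
    if (anyDuplicated(d)) stop("duplicated dates in input")
    if (is.unsorted(d, strictly = TRUE)) stop("dates must be sorted increasing")
    if (any(diff(d) != 1L)) stop("date index has gaps; lag_mean needs a gap-free series")
  }
  n <- length(x)
  if (n == 0L) return(numeric(0))
  mat <- vapply(lags, function(L) {
    if (L >= n) rep(NA_real_, n) else c(rep(NA_real_, L), x[seq_len(n - L)])
  }, numeric(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  rowMeans(mat)
}

#' Natural-log transform for right-skewed non-negative series
#'
#' Returns `log(x + offset)`. For precipitation an offset of 1 mm is used
#' (around half of warm-season days are rain-free); for pollutant
#' concentrations the offset is 0 and values below `floor` are raised to
#' `floor` so the log stays finite.
#'
#' @param x non-negative numeric vector
#' @param offset additive offset (default 0)
#' @param floor positive guard applied when `offset == 0`
#' @return `log(x + offset)` with `NA` propagated
#' @export
log_transform_skewed <- function(x, offset = 0, floor = 1e-6) {
  y <- if (offset == 0) pmax(x, floor) else x + offset
  if (any(y <= 0, na.rm = TRUE)) {
    stop("log transform undefined: x + offset <= 0 after floor guard")
  }
  log(y)
}

#' Restrict a dated table to warm-season months
#'
#' Keeps rows whose calendar month falls in `months` (default May through
#' September), preserving row order.
#'
#' @param table data frame with a `date` column of class `Date`
#' @param months integer months to retain
#' @return the filtered data frame
#' @export
restrict_warm_season <- function(table, months = 5:9) {
  stopifnot("date" %in% names(table))
  if (nrow(table) == 0L) return(table)
  keep <- (as.POSIXlt(table$date)$mon + 1L) %in% months
  table[keep, , drop = FALSE]
}

#' Empirical exposure percentiles
#'
#' Percentiles of the warm-season two-day-mean apparent temperature used as
#' the effect contrast (default: median and 95th percentile). Uses the
#' linear-interpolation convention (`stats::quantile` type 7), documented
#' because a different convention shifts the printed contrast by about
#' 0.1 degrees C.
#'
#' @param x numeric series (missing values dropped)
#' @param probs percentile probabilities
#' @return named numeric vector (`p50`, `p95`, ...)
#' @export
exposure_percentiles <- function(x, probs = c(0.5, 0.95)) {
  x <- x[is.finite(x)]
  if (length(x) < 20L) stop("need at least 20 non-missing values to estimate exposure percentiles")
  q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
  names(q) <- paste0("p", formatC(100 * probs, format = "fg"))
  q
}

#' Assemble the daily analysis series
#'
#' Joins daily meteorology and (optional) pollutant tables on date and adds
#' the derived exposure columns: apparent temperature `at_c`, its lag 0-1
#' mean `at2_c`, log-transformed precipitation / PM10 / NO2, day-of-year and
#' year. Lag means are computed inside contiguous calendar runs (so the
#' first day of each warm season, if preceded by a gap, has a missing
#' `at2_c` unless warm-up days are supplied). Lags are computed before any
#' season restriction: restrict afterwards so 1 May uses 30 April exposure.
#'
#' @param weather data frame: `date`, `temp_c`, `dewpoint_c`, `wind_ms`,
#'   `solar_wm2`, `precip_mm`
#' @param pollutants optional data frame: `date`, `o3_ppb`, `pm10_ugm3`,
#'   `no2_ppb` (missing values allowed)
#' @param precip_offset offset for the precipitation log transform (mm)
#' @return data frame, one row per day, ordered by date
#' @export
prepare_daily_series <- function(weather, pollutants = NULL, precip_offset = 1) {
  need <- c("date", "temp_c", "dewpoint_c", "wind_ms", "solar_wm2", "precip_mm")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather table missing columns: ", paste(miss, collapse = ", "))
  df <- weather[order(weather$date), need, drop = FALSE]
  if (anyDuplicated(df$date)) stop("duplicated dates in weather table")
  df$at_c <- apparent_temperature(df$temp_c, df$dewpoint_c)
  df$at2_c <- apply_by_run(df$at_c, df$date, lag_mean, lags = 0:1)
  df$ln_precip <- log_transform_skewed(df$precip_mm, offset = precip_offset)
  if (!is.null(pollutants)) {
    pneed <- c("o3_ppb", "pm10_ugm3", "no2_ppb")
    pm <- setdiff(c("date", pneed), names(pollutants))
    if (length(pm)) stop("pollutant table missing columns: ", paste(pm, collapse = ", "))
    idx <- match(df$date, pollutants$date)
    for (v in pneed) df[[v]] <- pollutants[[v]][idx]
    df$ln_pm10 <- log_transform_skewed(df$pm10_ugm3, offset = 0, floor = 0.5)
    df$ln_no2 <- log_transform_skewed(df$no2_ppb, offset = 0, floor = 0.5)
  }
  df$doy <- day_of_year(df$date)
  df$year <- calendar_year(df$date)
  rownames(df) <- NULL
  df
}
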