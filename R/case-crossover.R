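# Time-stratified case-crossover sensitivity analysis: fixed calendar
# strata, within-stratum referents (weekday-matched by default), and
# count-weighted conditional logistic estimation of the odds ratio at the
# same apparent-temperature contrast as the time-series model.

#' Build referent sets under a time-stratified design
#'
#' The study calendar is partitioned into fixed strata — 2- or 3-week
#' blocks anchored at the first study date, or calendar months — and each
#' case day's referents are the other eligible days in its stratum (the
#' same weekday only, when matched; weekday matching controls weekly
#' patterns and is on by default). Case days whose stratum offers no
#' eligible referent are dropped and counted.
#'
#' @param case_dates `Date` vector of case days
#' @param stratum_rule `"two_week"`, `"three_week"` or `"month"`
#' @param weekday_matched match referents on weekday (default `TRUE`)
#' @param calendar eligible referent days (default: the case days
#'   themselves, i.e. the observed study calendar)
#' @return data frame of class `referent_sets` with columns `set`,
#'   `case_date`, `referent_date` (one row per case-referent pair);
#'   attributes `dropped` (cases without referents) and `rule`
#' @export
build_referents <- function(case_dates,
                            stratum_rule = c("two_week", "three_week", "month"),
                            weekday_matched = TRUE, calendar = NULL) {
  stratum_rule <- match.arg(stratum_rule)
  if (is.null(calendar)) calendar <- case_dates
  calendar <- sort(unique(calendar))
  case_dates <- sort(unique(case_dates))
  start <- min(calendar)
  stratum_of <- function(d) {
    switch(stratum_rule,
           two_week = as.integer(d - start) %/% 14L,
           three_week = as.integer(d - start) %/% 21L,
           month = as.POSIXlt(d)$year * 12L + as.POSIXlt(d)$mon)
  }
  cal_str <- stratum_of(calendar)
  cal_wd <- as.POSIXlt(calendar)$wday
  case_str <- stratum_of(case_dates)
  case_wd <- as.POSIXlt(case_dates)$wday
  sets <- vector("list", length(case_dates))
  dropped <- as.Date(character(0))
  for (i in seq_along(case_dates)) {
    elig <- cal_str == case_str[i] & calendar != case_dates[i]
    if (weekday_matched) elig <- elig & cal_wd == case_wd[i]
    refs <- calendar[elig]
    if (length(refs) == 0L) {
      dropped <- c(dropped, case_dates[i])
    } else {
      sets[[i]] <- data.frame(set = i, case_date = case_dates[i],
                              referent_date = refs)
    }
  }
  out <- do.call(rbind, sets)
  if (is.null(out)) out <- data.frame(set = integer(0),
                                      case_date = as.Date(character(0)),
                                      referent_date = as.Date(character(0)))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "rule") <- stratum_rule
  attr(out, "weekday_matched") <- weekday_matched
  class(out) <- c("referent_sets", class(out))
  out
}

#' Conditional logistic fit of the case-crossover odds ratio
#'
#' Each matched set holds the case day (outcome 1) and its referent days
#' (outcome 0); the set is weighted by the case day's count, since cases
#' are aggregate daily counts. The conditional likelihood is maximised as
#' a stratified Cox partial likelihood (Breslow ties; exact with one case
#' per set). Exposure enters with the same linear-plus-hinge
#' apparent-temperature terms as the time-series model, and the odds
#' ratio is reported at the same p95-vs-p50 contrast.
#'
#' @param referents a [build_referents()] result
#' @param series daily exposure series (must cover case and referent days)
#' @param counts data frame `date`, `count` of daily case counts
#' @param at_knot_c hinge location; default the empirical median of the
#'   analysis-day exposure
#' @param contrast optional `c(at_ref, at_hi)`; default empirical p50/p95
#' @return list of class `cc_fit`: `or` (odds ratio at the contrast),
#'   `coefficients`, `contrast`, `at_knot`, `n_sets`, `fit`
#' @export
fit_conditional_logistic <- function(referents, series, counts,
                                     at_knot_c = NULL, contrast = NULL) {
  at <- series$at2_c[match(referents$case_date, series$date)]
  at_ref_day <- series$at2_c[match(referents$referent_date, series$date)]
  if (anyNA(at) || anyNA(at_ref_day)) {
    stop("exposure missing on some case or referent days")
  }
  obs_at <- series$at2_c[series$date %in% unique(referents$case_date)]
  if (is.null(at_knot_c)) at_knot_c <- unname(stats::quantile(obs_at, 0.5, type = 7))
  if (is.null(contrast)) {
    q <- exposure_percentiles(obs_at)
    contrast <- c(q[["p50"]], q[["p95"]])
  }
  cnt <- counts$count[match(referents$case_date, counts$date)]
  keep <- !is.na(cnt) & cnt > 0
  referents <- referents[keep, , drop = FALSE]
  at <- at[keep]; at_ref_day <- at_ref_day[keep]; cnt <- cnt[keep]

  long <- data.frame(
    set = rep(referents$set, 2L),
    y = rep(c(1L, 0L), each = nrow(referents)),
    at2 = c(at, at_ref_day),
    w = rep(cnt, 2L))
  long$hinge <- pmax(0, long$at2 - at_knot_c)
  long$t <- 1
  fit <- survival::coxph(
    survival::Surv(t, y) ~ at2 + hinge + survival::strata(set),
    data = long, weights = w, ties = "breslow")
  b <- stats::coef(fit)
  b[is.na(b)] <- 0  # no within-set exposure variation: flat likelihood
  h <- function(a) max(0, a - at_knot_c)
  or <- unname(exp(b["at2"] * (contrast[2] - contrast[1]) +
                     b["hinge"] * (h(contrast[2]) - h(contrast[1]))))
  structure(list(or = or, coefficients = b,
                 contrast = c(at_ref_c = contrast[1], at_hi_c = contrast[2]),
                 at_knot = at_knot_c,
                 n_sets = length(unique(referents$set)), fit = fit),
            class = "cc_fit")
}

#' Case-crossover sensitivity analysis against the time-series estimate
#'
#' Convenience wrapper: builds referents from the days with at least one
#' case, fits the conditional logistic model, and returns the odds ratio
#' next to a supplied time-series relative risk for comparison.
#'
#' @param series daily exposure series
#' @param counts data frame `date`, `count`
#' @param stratum_rule,weekday_matched see [build_referents()]
#' @param rr_time_series optional time-series RR at the same contrast
#' @param contrast optional `c(at_ref, at_hi)`
#' @return data frame: `stratum_rule`, `weekday_matched`, `or`,
#'   `rr_time_series`, `n_sets`, `n_dropped`
#' @export
case_crossover_analysis <- function(series, counts,
                                    stratum_rule = "two_week",
                                    weekday_matched = TRUE,
                                    rr_time_series = NA_real_,
                                    contrast = NULL) {
  case_days <- counts$date[counts$count > 0]
  refs <- build_referents(case_days, stratum_rule, weekday_matched,
                          calendar = series$date[!is.na(series$at2_c)])
  fit <- fit_conditional_logistic(refs, series, counts, contrast = contrast)
  data.frame(stratum_rule = stratum_rule, weekday_matched = weekday_matched,
             or = fit$or, rr_time_series = rr_time_series,
             n_sets = fit$n_sets, n_dropped = length(attr(refs, "dropped")))
}
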