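# End-to-end pipeline: simulate or ingest, prepare, impute, fit total
# effects across knot settings, mediate, interactions, case-crossover,
# and write publication-shaped summary tables with full-precision internals
# (rounding happens only at write time).

#' Pipeline configuration
#'
#' Either a scenario name (synthetic run) or paths to input CSVs, plus
#' every module parameter. All seeds are explicit; nothing is seeded from
#' the wall clock. The configuration round-trips unchanged through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param scenario synthetic scenario name, or `NULL` when paths are given
#' @param paths named list of input CSVs (`weather`, `pollutants`,
#'   `births`, optionally `weather_secondary`)
#' @param n_years simulated years (synthetic runs)
#' @param doy_knots_sweep day-of-year interior-knot settings for the
#'   sensitivity sweep
#' @param doy_knots knots for the main (covariate-adjusted) models
#' @param at_knot_c optional fixed hinge location
#' @param covariates confounder set for the adjusted models
#' @param precip_offset precipitation log offset, mm
#' @param m,burn_ins imputation count and burn-in sweeps
#' @param scheme inverse-odds weight scheme
#' @param n_boot,n_boot_reri bootstrap sizes (effect and RERI CIs)
#' @param cc_stratum_rule,cc_weekday_matched case-crossover settings
#' @param seed master integer seed; stage seeds are small fixed offsets
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(scenario = "no_mediation", paths = NULL,
                            n_years = 11L,
                            doy_knots_sweep = c(2L, 5L, 8L), doy_knots = 5L,
                            at_knot_c = NULL,
                            covariates = c("solar", "wind", "ln_precip"),
                            precip_offset = 1,
                            m = 3L, burn_ins = 2L,
                            scheme = "literal_eq1",
                            n_boot = 500L, n_boot_reri = 1000L,
                            cc_stratum_rule = "two_week",
                            cc_weekday_matched = TRUE,
                            seed = 1L) {
  cfg <- list(scenario = scenario, paths = paths, n_years = as.integer(n_years),
              doy_knots_sweep = as.integer(doy_knots_sweep),
              doy_knots = as.integer(doy_knots), at_knot_c = at_knot_c,
              covariates = covariates, precip_offset = precip_offset,
              m = as.integer(m), burn_ins = as.integer(burn_ins),
              scheme = scheme, n_boot = as.integer(n_boot),
              n_boot_reri = as.integer(n_boot_reri),
              cc_stratum_rule = cc_stratum_rule,
              cc_weekday_matched = cc_weekday_matched,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @param path JSON file path
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
  cfg
}

#' Demographic summary table (counts and percentages)
#'
#' Per categorical column: level counts and `100 * count / total` rounded
#' to one decimal, with missing values reported as their own `Missing`
#' level. An optional `count` column weights rows (pre-aggregated input).
#'
#' @param records data frame of categorical columns (plus optional `count`)
#' @param vars columns to tabulate (default: all non-count, non-date)
#' @return data frame `variable`, `level`, `n`, `pct`
#' @export
summarize_demographics <- function(records, vars = NULL) {
  if (nrow(records) == 0L) stop("summary error: empty input")
  w <- if ("count" %in% names(records)) records$count else rep(1L, nrow(records))
  if (is.null(vars)) vars <- setdiff(names(records), c("count", "date"))
  total <- sum(w)
  out <- lapply(vars, function(v) {
    x <- records[[v]]
    x <- ifelse(is.na(x), "Missing", as.character(x))
    tab <- tapply(w, x, sum)
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.numeric(tab) / total, 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exposure summary table
#'
#' Per exposure variable: N non-missing, median, mean (geometric for the
#' flagged right-skewed variables), min and max; includes the
#' excess-above-threshold exposure (`max(0, AT2 - threshold)`) as its own
#' variable.
#'
#' @param series daily analysis series
#' @param threshold hinge location for the excess variable (default
#'   empirical median of `at2_c`)
#' @param precip_offset offset used for the precipitation geometric mean
#' @return data frame `variable`, `n`, `median`, `mean`, `min`, `max`,
#'   `geometric`
#' @export
summarize_exposures <- function(series, threshold = NULL, precip_offset = 1) {
  if (nrow(series) == 0L) stop("summary error: empty series")
  if (is.null(threshold)) {
    threshold <- unname(stats::quantile(series$at2_c, 0.5, type = 7, na.rm = TRUE))
  }
  vars <- list(
    list("Two-day mean apparent temperature, C", series$at2_c, FALSE, 0),
    list("Two-day mean apparent temperature excess above threshold, C",
         pmax(0, series$at2_c - threshold), FALSE, 0),
    list("Mean solar radiation (W/m2)", series$solar_wm2, FALSE, 0),
    list("Total precipitation (mm)", series$precip_mm, TRUE, precip_offset),
    list("Mean wind speed (m/s)", series$wind_ms, FALSE, 0))
  if ("o3_ppb" %in% names(series)) {
    vars <- c(vars, list(
      list("Maximum 8 hour average ozone (ppb)", series$o3_ppb, FALSE, 0),
      list("Mean PM10 (ug/m3)", series$pm10_ugm3, TRUE, 0),
      list("Mean NO2 (ppb)", series$no2_ppb, TRUE, 0)))
  }
  rows <- lapply(vars, function(v) {
    x <- v[[2]]
    xv <- x[!is.na(x)]
    data.frame(variable = v[[1]], n = length(xv),
               median = stats::median(xv),
               mean = if (v[[3]]) geometric_mean(xv, offset = v[[4]]) else mean(xv),
               min = min(xv), max = max(xv), geometric = v[[3]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# indicator table -> readable demographic records for the summary table
.births_to_records <- function(births) {
  lvl <- function(x, yes, no) ifelse(x == 1, yes, no)
  age <- ifelse(births$age16_19 == 1, "16-19 years",
         ifelse(births$age30plus == 1, "30 years or older", "20-29 years"))
  data.frame(
    race = lvl(births$black, "Black", "Non-black"),
    age_group = age,
    smoking = lvl(births$smoker, "Smoker", "Non-smoker"),
    prenatal_care = lvl(births$low_prenatal, "Late or no prenatal care",
                        "Prenatal care"),
    education = lvl(births$no_hs, "Less than high school",
                    "High school or higher"),
    count = births$count)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest CSVs) -> prepare -> impute -> total-effect
#' knot-sensitivity sweep plus covariate-adjusted model -> mediation ->
#' interactions (RERI) -> case-crossover -> report. Writes
#' demographic/exposure/effect/RERI tables as CSV, a mediation
#' decomposition JSON and a run log into `out_dir`. Any stage failure
#' aborts with the stage name; partial outputs written so far persist.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @return results bundle (list) invisibly: `tables`, `mediation`,
#'   `truth` (synthetic runs), `log`
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("heatptb ", as.character(utils::packageVersion("heatptb"))),
                 paste0("R ", R.version.string),
                 paste0("seed ", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate / ingest ------------------------------------------------
  truth <- NULL
  if (!is.null(config$paths)) {
    inputs <- stage("ingest", {
      weather <- utils::read.csv(config$paths$weather, colClasses = c(date = "Date"))
      if (!is.null(config$paths$weather_secondary)) {
        sec <- utils::read.csv(config$paths$weather_secondary,
                               colClasses = c(date = "Date"))
        weather <- backfill_station(weather, sec)
        log_lines <- c(log_lines, paste0(
          "backfill: days missing at both stations: ",
          sum(unlist(attr(weather, "missing_both")))))
      }
      pollutants <- utils::read.csv(config$paths$pollutants,
                                    colClasses = c(date = "Date"))
      births <- utils::read.csv(config$paths$births, colClasses = c(date = "Date"))
      list(weather = weather, pollutants = pollutants, births = births)
    })
  } else {
    inputs <- stage("simulate", {
      scfg <- scenario_config(config$scenario, n_years = config$n_years,
                              seed = config$seed,
                              missing_frac = if (config$scenario == "null") 0 else 0.1)
      ds <- simulate_dataset(scfg)
      truth <- ds$truth
      list(weather = ds$weather, pollutants = ds$pollutants, births = ds$births)
    })
  }

  # -- prepare ----------------------------------------------------------
  prepared <- stage("prepare", {
    s <- prepare_daily_series(inputs$weather, inputs$pollutants,
                              precip_offset = config$precip_offset)
    s <- restrict_warm_season(s)
    s <- s[!is.na(s$at2_c), , drop = FALSE]
    s
  })
  counts_df <- stage("prepare", daily_counts(inputs$births))
  keep <- prepared$date %in% counts_df$date
  prepared <- prepared[keep, , drop = FALSE]
  counts <- counts_df$count[match(prepared$date, counts_df$date)]
  log_lines <- c(log_lines,
                 paste0("analysis days: ", nrow(prepared)),
                 paste0("missing pollutant cells: ",
                        sum(is.na(prepared[, c("o3_ppb", "pm10_ugm3", "no2_ppb")]))))

  # -- impute -----------------------------------------------------------
  imp <- stage("impute", mice_impute(prepared, m = config$m,
                                     burn_ins = config$burn_ins,
                                     seed = config$seed + 11L))
  completed <- imp$completed

  # -- demographic and exposure summary tables ---------------------------
  tab1 <- stage("report", summarize_demographics(.births_to_records(inputs$births)))
  tab2 <- stage("report", summarize_exposures(completed[[1]],
                                              precip_offset = config$precip_offset))
  utils::write.csv(tab1, file.path(out_dir, "table1_demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(format(tab2, digits = 4),
                   file.path(out_dir, "table2_exposures.csv"), row.names = FALSE)

  # -- total effects: knot sweep + adjusted model ------------------------
  q <- exposure_percentiles(prepared$at2_c)
  contrast <- c(q[["p50"]], q[["p95"]])
  sweep <- stage("fit-total", {
    rows <- list()
    for (k in config$doy_knots_sweep) {
      est <- bootstrap_effect(completed[[1]], counts,
                              model_spec(doy_knots = k, covariates = character(0),
                                         at_knot_c = config$at_knot_c),
                              n_boot = config$n_boot,
                              seed = config$seed + 20L + k, contrast = contrast)
      rows[[length(rows) + 1L]] <- data.frame(
        model = length(rows) + 1L, doy_knots = k, covariates = "None",
        rr = est$rr, rr_lo = est$ci_rr[1], rr_hi = est$ci_rr[2],
        af = est$af_percent, af_lo = est$ci_af[1], af_hi = est$ci_af[2])
    }
    rows
  })
  spec_adj <- model_spec(doy_knots = config$doy_knots,
                         covariates = config$covariates,
                         at_knot_c = config$at_knot_c)
  total_adj <- stage("fit-total", {
    ests <- lapply(completed, function(s) {
      bootstrap_effect(s, counts, spec_adj, n_boot = 0L, contrast = contrast)
    })
    one <- bootstrap_effect(completed[[1]], counts, spec_adj,
                            n_boot = config$n_boot, seed = config$seed + 31L,
                            contrast = contrast)
    list(pooled_rr = mean(vapply(ests, `[[`, numeric(1), "rr")),
         pooled_af = mean(vapply(ests, `[[`, numeric(1), "af_percent")),
         ci_rr = one$ci_rr, ci_af = one$ci_af, fit = one$fit)
  })

  # -- mediation --------------------------------------------------------
  med <- stage("mediate", mediate(completed, counts, spec_adj,
                                  scheme = config$scheme,
                                  n_boot = config$n_boot,
                                  seed = config$seed + 41L, contrast = contrast))
  tab3 <- do.call(rbind, c(sweep, list(
    data.frame(model = length(sweep) + 1L, doy_knots = config$doy_knots,
               covariates = paste(config$covariates, collapse = "+"),
               rr = total_adj$pooled_rr, rr_lo = total_adj$ci_rr[1],
               rr_hi = total_adj$ci_rr[2], af = total_adj$pooled_af,
               af_lo = total_adj$ci_af[1], af_hi = total_adj$ci_af[2]),
    data.frame(model = length(sweep) + 2L, doy_knots = config$doy_knots,
               covariates = paste(c(config$covariates, "inverse-odds weights"),
                                  collapse = "+"),
               rr = med$rr_direct, rr_lo = NA_real_, rr_hi = NA_real_,
               af = med$direct_af, af_lo = med$cis$direct[1],
               af_hi = med$cis$direct[2]))))
  num <- vapply(tab3, is.numeric, logical(1))
  tab3_out <- tab3
  tab3_out[num] <- lapply(tab3_out[num], round, digits = 3)
  utils::write.csv(tab3_out, file.path(out_dir, "table3_effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(total_af = med$total_af, direct_af = med$direct_af,
         indirect_af = med$indirect_af, cis = med$cis,
         scheme = med$weight_scheme, m_pooled = med$m_pooled,
         at_ref_c = med$at_ref_c, at_hi_c = med$at_hi_c),
    file.path(out_dir, "decomposition.json"), auto_unbox = TRUE, digits = NA)

  # exposure-response grid (stands in for the plotted curve)
  er <- exposure_response_table(total_adj$fit, at_ref_c = contrast[1])
  utils::write.csv(er, file.path(out_dir, "exposure_response.csv"),
                   row.names = FALSE)

  # -- interactions -----------------------------------------------------
  strata <- stage("interactions", expand_strata(inputs$births))
  tab4 <- stage("interactions", {
    suppressMessages(bootstrap_reri(strata, completed[[1]], spec_adj,
                                    n_boot = config$n_boot_reri,
                                    seed = config$seed + 51L,
                                    contrast = contrast))
  })
  tab4_out <- as.data.frame(tab4)
  tab4_out[-1] <- lapply(tab4_out[-1], round, digits = 3)
  utils::write.csv(tab4_out, file.path(out_dir, "table4_reri.csv"),
                   row.names = FALSE)

  # -- case-crossover ---------------------------------------------------
  cc <- stage("case-crossover",
              case_crossover_analysis(completed[[1]], counts_df,
                                      stratum_rule = config$cc_stratum_rule,
                                      weekday_matched = config$cc_weekday_matched,
                                      rr_time_series = total_adj$pooled_rr,
                                      contrast = contrast))
  utils::write.csv(cc, file.path(out_dir, "case_crossover.csv"),
                   row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(tables = list(table1 = tab1, table2 = tab2, table3 = tab3,
                               table4 = tab4, case_crossover = cc,
                               exposure_response = er),
                 mediation = med, truth = truth, log = log_lines))
}
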