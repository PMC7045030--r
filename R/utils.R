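# internal helpers shared across modules

# run id for contiguous daily blocks (lag windows must not cross gaps,
# e.g. the Sep -> May break between warm seasons)
contiguous_runs <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  if (length(dates) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(as.integer(dates)) != 1L)))
}

# apply a vector-valued function within contiguous date runs, preserving order
apply_by_run <- function(x, dates, fun, ...) {
  run <- contiguous_runs(dates)
  out <- rep(NA_real_, length(x))
  for (r in unique(run)) {
    idx <- which(run == r)
    out[idx] <- fun(x[idx], ...)
  }
  out
}

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

calendar_year <- function(dates) as.POSIXlt(dates)$year + 1900L

# seeded RNG in a local scope; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# numerically stable normalisation of log-weights to mean 1
normalise_log_weights <- function(logw) {
  m <- max(logw)
  w <- exp(logw - m)
  w / mean(w)
}

#' Geometric mean with an optional additive offset
#'
#' Computes `exp(mean(log(x + offset))) - offset`, the convention used for
#' right-skewed exposures (precipitation with many zero days, particle and
#' NO2 concentrations) in summary tables.
#'
#' @param x non-negative numeric vector
#' @param offset additive offset applied before the log and removed after
#' @param na.rm drop missing values
#' @return scalar geometric mean on the original scale
#' @export
geometric_mean <- function(x, offset = 0, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x + offset <= 0)) stop("geometric mean undefined: x + offset <= 0")
  exp(mean(log(x + offset))) - offset
}
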