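## Chilling and forcing rate functions and the season driver.
##
## All models share the over-threshold forcing rate
##     Rf = max(T - Tbf, 0) * (D / 12 h)^c
## with c = 0 (factor 1) for models 1-4.  Chill-day models (2, 3, 6, 7)
## count days with 0 <= T <= Tbc, the effective temperature range for apple
## development; model 4 uses the stepwise Utah weight scheme with negative
## weights for warm temperatures and a chilling state floored at zero.

## Utah weight band upper edges (deg C) and weights (Richardson scheme)
.utah_breaks <- c(1.4, 2.4, 9.1, 12.4, 15.9, 18.0)
.utah_weights <- c(0, 0.5, 1, 0.5, 0, -0.5, -1)

#' Chilling rate
#'
#' Daily (or hourly, model 4) chill units at temperature `T`.
#' Models 2, 3, 6, 7 accumulate one chill day when `0 <= T <= Tbc`;
#' model 4 uses the modified-Utah stepwise weights, including negative
#' contributions above the effective band.
#'
#' @param model model id in 2, 3, 4, 6, 7 (models 1 and 5 have no chilling
#'   phase and are rejected)
#' @param T air temperature, deg C (vectorised)
#' @param params a [pheno_params()] object for `model`
#' @return chill units, same length as `T`
#' @export
chill_rate <- function(model, T, params) {
  model <- as.integer(model)
  if (!model_uses_chilling(model))
    stop("model ", model, " has no chilling phase")
  if (model == 4L) {
    w <- .utah_weights[findInterval(T, .utah_breaks) + 1L]
    return(w)
  }
  as.numeric(T >= 0 & T <= params$Tbc)
}

#' Forcing rate
#'
#' `max(T - Tbf, 0)` growing-degree units, multiplied by the photoperiod
#' factor `(D / 12)^c` for the day-length-extended models 5-7.
#'
#' @param model model id, 1-7
#' @param T air temperature, deg C (vectorised)
#' @param D day length in hours (vectorised or scalar); ignored by models 1-4
#' @param params a [pheno_params()] object for `model`
#' @return forcing units, same length as `T`
#' @export
force_rate <- function(model, T, D, params) {
  model <- as.integer(model)
  r <- pmax(T - params$Tbf, 0)
  if (model >= 5L) r <- r * daylength_factor(D, params$c)
  r
}

## cumulative sum floored at zero: S_t = max(0, S_{t-1} + r_t)
cumsum_floor0 <- function(r) {
  s <- cumsum(r)
  s - pmin(cummin(s), 0)
}

## Fast season core.  tmean and D are vectors over one phenological year
## (index 1 = Aug 1); returns season indices of chilling completion (i1),
## bloom (i2) and the unfulfilled flag, without any validation.
season_core <- function(model, params, tmean, D, chill_daily = NULL) {
  n <- length(tmean)
  i1 <- NA_integer_; i2 <- NA_integer_
  if (model == 1L || model == 5L) {
    i1 <- if (model == 1L) season_jan1_index()
          else sidx_from_doy(as.integer(round(params$t1)))
    if (i1 > n) return(list(i1 = NA_integer_, i2 = NA_integer_,
                            unfulfilled = TRUE))
    rf <- pmax(tmean - params$Tbf, 0)
    if (model == 5L) rf <- rf * daylength_factor(D, params$c)
    sf <- cumsum(rf[i1:n])
    hit <- which(sf >= params$Fcrit)
    if (length(hit)) i2 <- i1 + hit[1L] - 1L
    return(list(i1 = i1, i2 = i2, unfulfilled = is.na(i2)))
  }
  ## chilling models; chilling starts Aug 1 (t0)
  if (model == 4L) {
    rc <- if (!is.null(chill_daily)) chill_daily
          else .utah_weights[findInterval(tmean, .utah_breaks) + 1L]
    sc <- cumsum_floor0(rc)
  } else {
    rc <- as.numeric(tmean >= 0 & tmean <= params$Tbc)
    sc <- cumsum(rc)
  }
  hit1 <- which(sc >= params$Ccrit)
  if (!length(hit1)) return(list(i1 = NA_integer_, i2 = NA_integer_,
                                 unfulfilled = TRUE))
  i1 <- hit1[1L]
  rf <- pmax(tmean - params$Tbf, 0)
  if (model >= 6L) rf <- rf * daylength_factor(D, params$c)
  if (model %in% c(2L, 4L, 6L)) {
    ## sequential: forcing accumulates from the chilling-completion day
    fcrit <- if (model == 4L) params$Fcrit
             else params$a * exp(params$b * sc[i1])
    sf <- cumsum(rf[i1:n])
    hit <- which(sf >= fcrit)
    if (length(hit)) i2 <- i1 + hit[1L] - 1L
  } else {
    ## parallel: forcing accumulates from t0, gated by the chilling
    ## fraction; the forcing requirement relaxes as chilling accrues
    gate <- pmin(sc / params$Ccrit, 1)
    sf <- cumsum(gate * rf)
    thr <- params$a * exp(params$b * sc)
    hit <- which(sf >= thr & seq_len(n) >= i1)
    if (length(hit)) i2 <- hit[1L]
  }
  list(i1 = i1, i2 = i2, unfulfilled = is.na(i2))
}

#' Run one phenological model through one season
#'
#' Executes the chilling and forcing accumulation of a model over one
#' phenological year (August 1 of the previous calendar year through
#' July 31) and returns the chilling-completion and bloom days.
#'
#' @param model model id, 1-7
#' @param params a [pheno_params()] object for `model`
#' @param season data frame with columns `date` (daily, complete season)
#'   and `tmean` (deg C)
#' @param latitude degrees north, used for the photoperiod of models 5-7
#' @param chill_daily optional numeric vector (one value per season day)
#'   of externally computed daily chill increments, e.g. hourly-resolution
#'   Utah units aggregated with [utah_chill_from_hourly()]; only model 4
#'   accepts it (Utah chilling is classically evaluated hourly)
#' @return an object of class `bloom_result`: list with elements `t1`
#'   (DOY of chilling completion, `NA` if never reached), `t2` (DOY of
#'   bloom, `NA` if none), `t1_index`/`t2_index` (day index within the
#'   season, 1 = Aug 1), and `unfulfilled` (no bloom by July 31)
#' @examples
#' cfg <- scenario_config(n_runs = 1, n_grid = 1, years = c(2000, 2001),
#'                        seed = 1)
#' ens <- gen_climate_ensemble(cfg)
#' season <- split_seasons(ens)[["2001"]]
#' run_season(2, default_pheno_params(2), season, latitude = 52.5)
#' @export
run_season <- function(model, params, season, latitude = 52.5,
                       chill_daily = NULL) {
  model <- as.integer(model)
  stopifnot(inherits(params, "pheno_params"), params$model == model)
  if (nrow(season) < 365L)
    stop("season must cover a full phenological year (Aug 1 - Jul 31)")
  if (!is.null(chill_daily)) {
    if (model != 4L)
      stop("external chill increments are only supported for model 4")
    stopifnot(length(chill_daily) == nrow(season))
  }
  D <- compute_daylength(latitude, doy_of(season$date))
  res <- season_core(model, params, season$tmean, D, chill_daily)
  doy <- doy_of(season$date)
  structure(list(
    t1 = if (is.na(res$i1)) NA_integer_ else doy[res$i1],
    t2 = if (is.na(res$i2)) NA_integer_ else doy[res$i2],
    t1_index = res$i1, t2_index = res$i2,
    unfulfilled = res$unfulfilled
  ), class = "bloom_result")
}

#' @export
print.bloom_result <- function(x, ...) {
  cat("bloom_result: t1 =", x$t1, " t2 =", x$t2,
      if (x$unfulfilled) " (unfulfilled chilling / no bloom)", "\n")
  invisible(x)
}

#' Daily Utah chill units from an hourly series
#'
#' Aggregates hourly temperatures to daily modified-Utah chill
#' increments (sum of hourly weights divided by 24, so a full day inside
#' the optimal band yields one unit on the daily scale used by
#' [run_season()]).
#'
#' @param hourly data frame with columns `date` and `temp` (24 rows per
#'   day, e.g. from [daily_to_hourly()])
#' @return data frame `date`, `chill` (one row per day)
#' @export
utah_chill_from_hourly <- function(hourly) {
  w <- .utah_weights[findInterval(hourly$temp, .utah_breaks) + 1L]
  agg <- tapply(w, hourly$date, function(v) sum(v) / 24)
  data.frame(date = as.Date(names(agg)), chill = as.numeric(agg),
             row.names = NULL)
}

#' Run a model through every season of a daily series
#'
#' @inheritParams run_season
#' @param temps data frame with `date` and `tmean` covering several
#'   phenological years; incomplete seasons at the edges are dropped
#' @return data frame with one row per complete season: `year`, `t1`,
#'   `t2`, `t1_index`, `t2_index`, `unfulfilled`
#' @export
run_seasons <- function(model, params, temps, latitude = 52.5) {
  seasons <- split_seasons(temps)
  out <- lapply(seasons, function(s)
    run_season(model, params, s, latitude))
  data.frame(
    year = as.integer(names(seasons)),
    t1 = vapply(out, function(r) as.integer(r$t1), integer(1L)),
    t2 = vapply(out, function(r) as.integer(r$t2), integer(1L)),
    t1_index = vapply(out, function(r) as.integer(r$t1_index), integer(1L)),
    t2_index = vapply(out, function(r) as.integer(r$t2_index), integer(1L)),
    unfulfilled = vapply(out, function(r) r$unfulfilled, logical(1L)),
    row.names = NULL
  )
}
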