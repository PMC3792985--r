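## Bound-constrained simulated-annealing calibration of the phenological
## models, with leave-one-out and external cross-validation.

## free parameters and bounds per model; t1 of model 5 is searched in
## season-index space (1 = Aug 1) and reported as a calendar DOY
.fit_bounds <- list(
  `1` = list(names = c("Tbf", "Fcrit"),
             lower = c(0, 10), upper = c(10, 500)),
  `2` = list(names = c("Tbf", "Tbc", "Ccrit", "a", "b"),
             lower = c(0, 0, 10, 20, -0.03),
             upper = c(10, 10, 150, 2000, 0)),
  `3` = list(names = c("Tbf", "Tbc", "Ccrit", "a", "b"),
             lower = c(0, 0, 10, 20, -0.03),
             upper = c(10, 10, 150, 2000, 0)),
  `4` = list(names = c("Tbf", "Tbc", "Ccrit", "Fcrit"),
             lower = c(0, 0, 10, 10), upper = c(10, 10, 150, 600)),
  `5` = list(names = c("Tbf", "Fcrit", "c", "t1s"),
             lower = c(0, 10, 0, 1), upper = c(10, 500, 2, 220)),
  `6` = list(names = c("Tbf", "Tbc", "Ccrit", "a", "b", "c"),
             lower = c(0, 0, 10, 20, -0.03, 0),
             upper = c(10, 10, 150, 2000, 0, 2)),
  `7` = list(names = c("Tbf", "Tbc", "Ccrit", "a", "b", "c"),
             lower = c(0, 0, 10, 20, -0.03, 0),
             upper = c(10, 10, 150, 2000, 0, 2))
)

## vector -> pheno_params
.vec_to_params <- function(model, v, nm) {
  p <- as.list(v); names(p) <- nm
  if (model == 5L) {
    sidx <- as.integer(round(p$t1s))
    p$t1s <- NULL
    ## season index back to calendar DOY (1 = Aug 1 = DOY 213)
    p$t1 <- if (sidx <= 153L) sidx + 212L else sidx - 153L
  }
  do.call(pheno_params, c(list(model = model), p))
}

## objective: RMSE over usable seasons; seasons where the model projects
## no bloom contribute a fixed 100 d error so the objective stays finite
## and degenerate parameter sets are penalised
.sa_objective <- function(model, v, nm, tm_list, D_list, doy_list,
                          obs_doy, no_bloom_penalty = 100) {
  p <- tryCatch(.vec_to_params(model, v, nm), error = function(e) NULL)
  if (is.null(p)) return(Inf)
  err2 <- 0; nuse <- 0L
  for (j in seq_along(tm_list)) {
    if (is.na(obs_doy[j])) next
    r <- season_core(model, p, tm_list[[j]], D_list[[j]])
    nuse <- nuse + 1L
    if (is.na(r$i2)) {
      err2 <- err2 + no_bloom_penalty^2
    } else {
      err2 <- err2 + (doy_list[[j]][r$i2] - obs_doy[j])^2
    }
  }
  if (nuse == 0L) return(Inf)
  sqrt(err2 / nuse)
}

## one bound-constrained simulated-annealing chain (geometric cooling,
## Gaussian proposals reflected into the bounds), returns best-so-far
.sa_chain <- function(fn, lower, upper, x0, iters, t0, cooling,
                      step0 = 0.25) {
  width <- upper - lower
  x <- x0; fx <- fn(x)
  best <- x; fbest <- fx
  temp <- t0
  for (k in seq_len(iters)) {
    frac <- k / iters
    step <- step0 * (1 - 0.9 * frac)      # shrink proposals as we cool
    prop <- x + stats::rnorm(length(x), sd = step * width)
    ## reflect into the bounds
    for (rep in 1:3) {
      prop <- ifelse(prop < lower, 2 * lower - prop, prop)
      prop <- ifelse(prop > upper, 2 * upper - prop, prop)
    }
    prop <- pmin(pmax(prop, lower), upper)
    fp <- fn(prop)
    if (is.finite(fp) &&
        (fp <= fx || stats::runif(1L) < exp((fx - fp) / temp))) {
      x <- prop; fx <- fp
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    temp <- temp * cooling
  }
  list(par = best, value = fbest)
}

#' Calibrate a phenological model to observed bloom dates
#'
#' Fits the free parameters of a phenological model to an annual series of
#' observed bloom days of year by bound-constrained simulated annealing,
#' minimising the root mean square error between observed and simulated
#' DOY.  Base temperatures are searched in 0-10 deg C, the effective
#' temperature range for apple development.  Seasons in which a candidate
#' parameter set projects no bloom contribute a fixed 100-day error.
#'
#' @param model model id, 1-7
#' @param obs data frame `year`, `doy` of observed bloom (NA allowed)
#' @param temps data frame `date`, `tmean` covering the observed seasons
#' @param latitude degrees north
#' @param sa_control list: `iters` per chain, `n_chains`, initial
#'   temperature `t0` (in objective units, days), `cooling` factor per
#'   step, `seed`
#' @return object of class `pheno_fit`: the calibrated [pheno_params()],
#'   the achieved `rmse` (days), number of seasons used, the best-so-far
#'   objective trace and the fitting metadata
#' @seealso [loo_prmse()], [external_prmse()], [predict.pheno_fit()]
#' @export
pheno_fit <- function(model, obs, temps, latitude = 52.5,
                      sa_control = list()) {
  model <- as.integer(model)
  ctrl <- utils::modifyList(
    list(iters = 4000L, n_chains = 2L, t0 = 20, cooling = NULL, seed = 1L),
    sa_control)
  if (is.null(ctrl$cooling))
    ctrl$cooling <- (0.01 / ctrl$t0)^(1 / ctrl$iters)
  seasons <- split_seasons(temps)
  yrs <- as.integer(names(seasons))
  obs_doy <- obs$doy[match(yrs, obs$year)]
  usable <- sum(!is.na(obs_doy))
  if (usable < 5L)
    stop("need at least 5 usable seasons, got ", usable)
  tm_list <- lapply(seasons, `[[`, "tmean")
  doy_list <- lapply(seasons, function(s) doy_of(s$date))
  D_list <- lapply(doy_list, function(d) compute_daylength(latitude, d))
  spec <- .fit_bounds[[as.character(model)]]
  fn <- function(v) .sa_objective(model, v, spec$names, tm_list, D_list,
                                  doy_list, obs_doy)
  set.seed(ctrl$seed)
  best <- NULL; trace <- numeric(0)
  for (ch in seq_len(ctrl$n_chains)) {
    x0 <- spec$lower + stats::runif(length(spec$lower)) *
      (spec$upper - spec$lower)
    res <- .sa_chain(fn, spec$lower, spec$upper, x0,
                     ctrl$iters, ctrl$t0, ctrl$cooling)
    trace <- c(trace, res$value)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value))
    stop("no sampled parameter set produced bloom in any season")
  params <- .vec_to_params(model, best$par, spec$names)
  structure(list(
    params = params, model = model, rmse = best$value,
    n_years = usable, latitude = latitude,
    chain_best = trace, sa_control = ctrl,
    obs = data.frame(year = yrs, doy = obs_doy)
  ), class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("Calibrated phenological model (simulated annealing)\n")
  print(x$params)
  cat(sprintf("  RMSE = %.2f d over %d seasons\n", x$rmse, x$n_years))
  invisible(x)
}

#' @export
summary.pheno_fit <- function(object, ...) {
  print(object)
  cat("  best objective per chain:",
      paste(sprintf("%.2f", object$chain_best), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.pheno_fit <- function(object, ...) {
  p <- object$params
  unlist(p[setdiff(names(p), "model")])
}

#' Predict bloom days from a calibrated model
#'
#' @param object a [pheno_fit()]
#' @param temps data frame `date`, `tmean`; defaults to refusing (supply
#'   the series to predict for)
#' @param ... unused
#' @return data frame `year`, `doy` of simulated bloom (`NA` when
#'   chilling/forcing stays unfulfilled)
#' @export
predict.pheno_fit <- function(object, temps, ...) {
  r <- run_seasons(object$model, object$params, temps, object$latitude)
  data.frame(year = r$year,
             doy = ifelse(r$unfulfilled, NA_integer_, r$t2))
}

#' @export
residuals.pheno_fit <- function(object, temps, ...) {
  pr <- predict(object, temps)
  m <- merge(object$obs, pr, by = "year", suffixes = c("_obs", "_sim"))
  stats::setNames(m$doy_sim - m$doy_obs, m$year)
}

#' Leave-one-out prediction RMSE
#'
#' Full cross-validation: each observed season is predicted from a model
#' calibrated on all remaining seasons; the root mean square of the
#' prediction errors is returned.
#'
#' @inheritParams pheno_fit
#' @return PRMSE in days; attribute `per_year` holds the fold errors
#' @export
loo_prmse <- function(model, obs, temps, latitude = 52.5,
                      sa_control = list()) {
  usable <- obs[!is.na(obs$doy), ]
  if (nrow(usable) < 6L) stop("need at least 6 usable seasons")
  errs <- rep(NA_real_, nrow(usable))
  for (i in seq_len(nrow(usable))) {
    train <- usable[-i, ]
    ctrl <- utils::modifyList(list(seed = 1L), sa_control)
    ctrl$seed <- ctrl$seed + i   # independent schedule per fold
    fit <- pheno_fit(model, train, temps, latitude, ctrl)
    pr <- predict(fit, temps)
    pdoy <- pr$doy[match(usable$year[i], pr$year)]
    errs[i] <- if (is.na(pdoy)) 100 else pdoy - usable$doy[i]
  }
  out <- sqrt(mean(errs^2))
  attr(out, "per_year") <- stats::setNames(errs, usable$year)
  out
}

#' External prediction RMSE at held-out locations
#'
#' Applies an already calibrated model to other locations and pools the
#' squared prediction errors.
#'
#' @param fitted a [pheno_fit()]
#' @param other_locations list of lists, each with elements `obs`
#'   (data frame `year`, `doy`) and `temps` (data frame `date`, `tmean`);
#'   optionally `latitude`
#' @return pooled PRMSE in days
#' @export
external_prmse <- function(fitted, other_locations) {
  stopifnot(inherits(fitted, "pheno_fit"))
  if (length(other_locations) < 1L)
    stop("need at least one held-out location")
  err2 <- 0; n <- 0L
  for (loc in other_locations) {
    lat <- if (!is.null(loc$latitude)) loc$latitude else fitted$latitude
    r <- run_seasons(fitted$model, fitted$params, loc$temps, lat)
    pdoy <- ifelse(r$unfulfilled, NA_integer_, r$t2)
    m <- match(loc$obs$year, r$year)
    for (i in seq_along(m)) {
      if (is.na(m[i]) || is.na(loc$obs$doy[i])) next
      e <- if (is.na(pdoy[m[i]])) 100 else pdoy[m[i]] - loc$obs$doy[i]
      err2 <- err2 + e^2; n <- n + 1L
    }
  }
  if (n == 0L) stop("no predictable observations at the held-out locations")
  sqrt(err2 / n)
}
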