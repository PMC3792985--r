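## Synthetic climate-ensemble and phenology generator.
##
## Emulates the statistical structure the projection chain assumes: an
## ensemble of warming daily temperature series (seasonal cycle + linear
## trend + run-specific bias + AR(1) noise) on a small grid, and annual
## bloom observations produced by a known phenological model plus rounded
## Gaussian observation noise.  It replaces external RCM runs and
## phenological-network data in all tests and demos.

#' Scenario configuration for the synthetic ensemble
#'
#' Defaults describe an A1B-like north-German scenario: annual-mean
#' temperature 9 deg C with an 8.5 K seasonal half-amplitude (January mean
#' near 0.5 deg C, July near 17.5 deg C), about +3 K warming per century
#' over 1951-2100, daily AR(1) weather noise, and a modest inter-run bias
#' spread.
#'
#' @param n_runs number of climate realizations
#' @param n_grid number of grid points
#' @param grid_lats latitudes (deg N) per grid point; recycled
#' @param grid_lons longitudes (deg E) per grid point; recycled
#' @param years integer vector `c(first, last)` of calendar years
#' @param seasonal_amplitude half-amplitude of the seasonal cycle, K
#' @param annual_mean annual-mean temperature, deg C
#' @param diurnal_range mean Tmean - Tmin offset is `diurnal_range / 2`, K
#' @param ar1_phi lag-1 autocorrelation of the daily noise, in `[0, 1)`
#' @param noise_sd innovation standard deviation of the AR(1) noise, K
#' @param tmin_noise_sd sd of the independent daily Tmin noise, K
#' @param warming_per_century linear warming rate, K per 100 years; scalar
#'   or one value per run
#' @param run_bias additive bias per run, K; defaults to an even spread
#'   over +/- 0.75 K
#' @param seed integer seed; the generator is bit-reproducible under it
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(n_runs = 5L,
                            n_grid = 4L,
                            grid_lats = seq(52, 53.5, length.out = n_grid),
                            grid_lons = seq(7, 10, length.out = n_grid),
                            years = c(1951L, 2100L),
                            seasonal_amplitude = 8.5,
                            annual_mean = 9,
                            diurnal_range = 8,
                            ar1_phi = 0.7,
                            noise_sd = 2,
                            tmin_noise_sd = 1,
                            warming_per_century = 3,
                            run_bias = NULL,
                            seed = 1L) {
  stopifnot(n_runs >= 1L, n_grid >= 1L)
  if (ar1_phi < 0 || ar1_phi >= 1)
    stop("ar1_phi must lie in [0, 1)")
  if (years[2L] < years[1L]) stop("empty year range")
  if (is.null(run_bias))
    run_bias <- if (n_runs == 1L) 0 else
      seq(-0.75, 0.75, length.out = n_runs)
  cfg <- list(
    n_runs = as.integer(n_runs), n_grid = as.integer(n_grid),
    grid_lats = rep_len(grid_lats, n_grid),
    grid_lons = rep_len(grid_lons, n_grid),
    years = as.integer(years),
    seasonal_amplitude = seasonal_amplitude, annual_mean = annual_mean,
    diurnal_range = diurnal_range, ar1_phi = ar1_phi,
    noise_sd = noise_sd, tmin_noise_sd = tmin_noise_sd,
    warming_per_century = rep_len(warming_per_century, n_runs),
    run_bias = rep_len(run_bias, n_runs),
    seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

## deterministic seasonal cycle: coldest around Jan 15, warmest mid-July
seasonal_cycle <- function(doy, annual_mean, amplitude) {
  annual_mean - amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

## AR(1) series with innovation sd `sd` (stationary start)
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd)
  if (phi == 0) return(e)
  init <- stats::rnorm(1L, sd = sd / sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive", init = init))
}

#' Generate a synthetic climate ensemble
#'
#' Daily mean and minimum temperature per run and grid point:
#' `tmean = annual mean + seasonal cycle + linear trend + run bias +
#' AR(1) noise`, `tmin = tmean - diurnal_range / 2 + independent noise`.
#' Calendars are complete (no gaps); generated `tmin` never exceeds
#' `tmean`.
#'
#' @param config a [scenario_config()]
#' @return long-format data frame with columns `run`, `grid_id`, `lat`,
#'   `lon`, `date`, `tmean`, `tmin`
#' @examples
#' ens <- gen_climate_ensemble(scenario_config(n_runs = 2, n_grid = 1,
#'                                             years = c(2000, 2002)))
#' head(ens)
#' @export
gen_climate_ensemble <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  dates <- seq.Date(as.Date(paste0(config$years[1L], "-01-01")),
                    as.Date(paste0(config$years[2L], "-12-31")), by = "day")
  nd <- length(dates)
  doy <- doy_of(dates)
  yrs_frac <- (as.numeric(dates) -
               as.numeric(dates[1L])) / 365.25
  clim <- seasonal_cycle(doy, config$annual_mean, config$seasonal_amplitude)
  out <- vector("list", config$n_runs * config$n_grid)
  k <- 0L
  for (r in seq_len(config$n_runs)) {
    trend <- config$warming_per_century[r] * yrs_frac / 100
    for (g in seq_len(config$n_grid)) {
      k <- k + 1L
      noise <- ar1_noise(nd, config$ar1_phi, config$noise_sd)
      tmean <- clim + trend + config$run_bias[r] + noise
      tmin <- pmin(tmean, tmean - config$diurnal_range / 2 +
                     stats::rnorm(nd, sd = config$tmin_noise_sd))
      out[[k]] <- data.frame(
        run = r, grid_id = g,
        lat = config$grid_lats[g], lon = config$grid_lons[g],
        date = dates, tmean = tmean, tmin = tmin)
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic bloom observations
#'
#' Runs a known ("true") phenological model through every season of a
#' temperature series and adds rounded Gaussian observation noise to the
#' bloom day of year.  Seasons in which the model never blooms are emitted
#' as `NA`.
#'
#' @param true_model model id, 1-7
#' @param true_params [pheno_params()] of the generating model
#' @param temps data frame with `date` and `tmean` for a single run and
#'   grid point
#' @param obs_noise_sd observation noise standard deviation, days
#' @param seed integer seed for the noise
#' @param latitude degrees north (photoperiod of models 5-7)
#' @return data frame `year`, `doy` (observed bloom DOY, `NA` when the
#'   model projects no bloom)
#' @export
gen_bloom_observations <- function(true_model, true_params, temps,
                                   obs_noise_sd = 2, seed = 1L,
                                   latitude = 52.5) {
  res <- run_seasons(true_model, true_params, temps, latitude)
  set.seed(seed)
  noise <- round(stats::rnorm(nrow(res), sd = obs_noise_sd))
  doy <- ifelse(res$unfulfilled, NA_integer_,
                as.integer(res$t2 + noise))
  if (all(is.na(doy)))
    warning("the generating model blooms in no season (all observations NA)")
  data.frame(year = res$year, doy = doy)
}
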