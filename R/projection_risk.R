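## Ensemble bloom projection, last spring freeze, blossom frost risk theta,
## unfulfilled-chilling fractions and kernel density summaries.

#' Project bloom across a climate ensemble
#'
#' Runs every requested phenological model through every season of every
#' (run, grid point) series of an ensemble.  Seasons without bloom are
#' recorded (`unfulfilled`), never dropped.
#'
#' @param ensemble long-format data frame as produced by
#'   [gen_climate_ensemble()] (columns `run`, `grid_id`, `lat`, `date`,
#'   `tmean`)
#' @param params_by_model named list of [pheno_params()] keyed by model id
#'   (single set shared across grid points) or, per model, a list keyed by
#'   grid id for per-grid-point calibrations
#' @param models integer model ids to project (default: all keys)
#' @return data frame with one row per run x model x grid x season:
#'   `run`, `model`, `grid_id`, `year`, `t1`, `t2`, `unfulfilled`
#' @export
project_bloom_ensemble <- function(ensemble, params_by_model,
                                   models = NULL) {
  if (is.null(models)) models <- as.integer(names(params_by_model))
  combos <- unique(ensemble[c("run", "grid_id")])
  out <- list(); k <- 0L
  for (i in seq_len(nrow(combos))) {
    sel <- ensemble$run == combos$run[i] &
      ensemble$grid_id == combos$grid_id[i]
    series <- ensemble[sel, ]
    lat <- series$lat[1L]
    for (m in models) {
      p <- params_by_model[[as.character(m)]]
      if (is.null(p)) stop("no parameters supplied for model ", m)
      if (!inherits(p, "pheno_params")) {
        p <- p[[as.character(combos$grid_id[i])]]
        if (is.null(p))
          stop("no parameters for model ", m, ", grid point ",
               combos$grid_id[i])
      }
      r <- run_seasons(m, p, series, lat)
      k <- k + 1L
      out[[k]] <- data.frame(run = combos$run[i], model = m,
                             grid_id = combos$grid_id[i],
                             year = r$year, t1 = r$t1, t2 = r$t2,
                             t1_index = r$t1_index, t2_index = r$t2_index,
                             unfulfilled = r$unfulfilled)
    }
  }
  do.call(rbind, out)
}

#' 30-year-window change of an annual field
#'
#' Mean over the target window minus mean over the reference window,
#' computed per group (e.g. per grid point).
#'
#' @param x data frame with a `year` column and a value column
#' @param value name of the value column
#' @param reference,target integer `c(first, last)` windows
#' @param by optional character vector of grouping columns
#' @param min_coverage minimum fraction of the window's years that must
#'   carry a non-missing value (default 0.75; seasons without bloom may
#'   be absent or `NA`, and warm late-century windows can lose a quarter
#'   of their seasons to unfulfilled chilling)
#' @return data frame of the grouping columns plus `delta`
#' @export
delta_30yr <- function(x, value, reference, target, by = NULL,
                       min_coverage = 0.75) {
  one <- function(d) {
    wmean <- function(w) {
      sel <- d$year >= w[1L] & d$year <= w[2L]
      v <- d[[value]][sel]
      need <- (w[2L] - w[1L] + 1L)
      if (sum(!is.na(v)) < min_coverage * need)
        stop("window ", w[1L], "-", w[2L],
             " has insufficient coverage")
      mean(v, na.rm = TRUE)
    }
    wmean(target) - wmean(reference)
  }
  if (is.null(by)) return(data.frame(delta = one(x)))
  groups <- split(x, x[by], drop = TRUE)
  res <- lapply(groups, function(d)
    cbind(unique(d[by]), delta = one(d)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Last spring freeze of one year
#'
#' The last day on or before July 31 (DOY 212) with a daily minimum
#' temperature at or below 0 deg C.
#'
#' @param tmin_df data frame `date`, `tmin` covering January 1 - July 31
#'   of one calendar year
#' @return DOY of the last spring freeze, or `NA` if the spring is
#'   frost-free
#' @export
last_spring_freeze <- function(tmin_df) {
  doy <- doy_of(tmin_df$date)
  need <- seq_len(212L)
  if (!all(need %in% doy))
    stop("tmin series must cover Jan 1 - Jul 31 completely")
  sel <- doy <= 212L & tmin_df$tmin <= 0
  if (!any(sel)) return(NA_integer_)
  max(doy[sel])
}

#' Blossom frost risk over a 30-year window
#'
#' The ratio of years, within a 30-year window, in which the daily minimum
#' temperature drops to or below the threshold `beta` between the bloom
#' day and July 31 (both ends inclusive).  Years without bloom cannot
#' incur blossom frost: they are excluded from the count but stay in the
#' fixed 30-year denominator.
#'
#' @param bloom data frame `year`, `doy` (bloom DOY, `NA` = no bloom)
#' @param tmin_df data frame `date`, `tmin` covering the window's springs
#' @param beta frost threshold in deg C, conventionally 0 (freeze) or 2
#'   (possible radiation-frost damage)
#' @param window integer `c(first, last)` years; must span 30 years unless
#'   `partial = TRUE`
#' @param partial allow windows shorter than 30 years, with a
#'   proportional denominator
#' @return theta in `[0, 1]`
#' @export
frost_risk_theta <- function(bloom, tmin_df, beta = 0,
                             window = NULL, partial = FALSE) {
  if (is.null(window)) window <- range(bloom$year)
  n_years <- window[2L] - window[1L] + 1L
  if (n_years != 30L && !partial)
    stop("window must span exactly 30 years (use partial = TRUE to ",
         "allow a proportional denominator)")
  yrs <- window[1L]:window[2L]
  tm_year <- as.integer(format(tmin_df$date, "%Y"))
  tm_doy <- doy_of(tmin_df$date)
  hits <- 0L
  for (y in yrs) {
    bd <- bloom$doy[match(y, bloom$year)]
    if (is.na(bd)) next                 # no bloom, no blossom frost
    sel <- tm_year == y & tm_doy >= bd & tm_doy <= 212L
    if (!any(sel)) next
    if (min(tmin_df$tmin[sel]) <= beta) hits <- hits + 1L
  }
  hits / n_years
}

#' Change in blossom frost risk
#'
#' @param theta_ref,theta_target risk values (or equally-shaped vectors)
#'   for the same grid points, threshold and stage
#' @return `theta_target - theta_ref`, in `[-1, 1]`
#' @export
delta_theta <- function(theta_ref, theta_target) {
  if (length(theta_ref) != length(theta_target))
    stop("theta fields must have the same length")
  theta_target - theta_ref
}

#' Fraction of years with unfulfilled chilling
#'
#' @param bloom_results data frame with `year` and `unfulfilled` columns
#'   (one model/run/grid combination)
#' @param window integer `c(first, last)` years
#' @return fraction of the window's years flagged unfulfilled
#' @export
unfulfilled_fraction <- function(bloom_results, window = NULL) {
  if (is.null(window)) window <- range(bloom_results$year)
  yrs <- window[1L]:window[2L]
  sel <- bloom_results$year %in% yrs
  if (!any(sel)) stop("window contains no seasons")
  flags <- bloom_results$unfulfilled[sel]
  sum(flags) / length(yrs)
}

#' Kernel density of risk changes
#'
#' Gaussian-kernel density estimate of a sample of blossom-frost-risk
#' changes (across grid points, runs and models), on a regular grid.
#' A bandwidth floor protects against zero-variance input.
#'
#' @param dtheta numeric sample (>= 2 values)
#' @param bw bandwidth; `NULL` for Silverman's rule with a floor of 0.005
#' @param n grid size
#' @return data frame `x`, `density`; integrates to one
#' @export
pmf_kde <- function(dtheta, bw = NULL, n = 512L) {
  dtheta <- dtheta[is.finite(dtheta)]
  if (length(dtheta) < 2L) stop("need at least 2 finite values")
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(dtheta), error = function(e) 0.005)
    bw <- max(bw, 0.005)
  }
  d <- stats::density(dtheta, bw = bw, n = n)
  data.frame(x = d$x, density = d$y)
}

#' Moving 30-year frost-risk series
#'
#' Convenience wrapper evaluating [frost_risk_theta()] on 30-year windows
#' stepping annually.
#'
#' @inheritParams frost_risk_theta
#' @param years integer `c(first, last)` span of window start years
#' @return data frame `window_start`, `window_end`, `theta`
#' @export
frost_risk_series <- function(bloom, tmin_df, beta = 0, years = NULL) {
  if (is.null(years)) years <- range(bloom$year)
  starts <- years[1L]:(years[2L] - 29L)
  theta <- vapply(starts, function(s)
    frost_risk_theta(bloom, tmin_df, beta, c(s, s + 29L)), numeric(1L))
  data.frame(window_start = starts, window_end = starts + 29L,
             theta = theta)
}
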