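## Calendar helpers shared across modules.
##
## The phenological year y runs from August 1 of calendar year y-1 through
## July 31 of calendar year y, so one winter chilling phase and the following
## spring forcing phase fall into the same season.

#' Day of year of a Date vector
#' @param date a `Date` vector
#' @return integer DOY, 1-based from January 1
#' @keywords internal
doy_of <- function(date) as.integer(format(date, "%j"))

#' Phenological year of a Date vector
#'
#' Days from August 1 onward belong to the next calendar year's season.
#'
#' @param date a `Date` vector
#' @return integer vector of phenological years
#' @export
pheno_year <- function(date) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y + as.integer(m >= 8L)
}

#' Split a daily series into complete phenological years
#'
#' @param x data frame with a `date` column (class `Date`), daily step
#' @return named list of data frames, one per complete season
#'   (Aug 1 through Jul 31), names are the phenological years
#' @export
split_seasons <- function(x) {
  stopifnot(inherits(x$date, "Date"))
  py <- pheno_year(x$date)
  out <- split(x, py)
  keep <- vapply(out, function(s) {
    m <- as.integer(format(s$date[1L], "%m"))
    d <- as.integer(format(s$date[1L], "%d"))
    ml <- as.integer(format(s$date[nrow(s)], "%m"))
    dl <- as.integer(format(s$date[nrow(s)], "%d"))
    m == 8L && d == 1L && ml == 7L && dl == 31L && nrow(s) >= 365L
  }, logical(1L))
  out[keep]
}

## index of January 1 within a season that starts August 1 (Aug-Dec = 153 d)
season_jan1_index <- function() 154L

## season index (1 = Aug 1) for a calendar DOY; DOY >= 213 lies in the
## autumn part of the season, DOY < 213 in the bloom-year part
sidx_from_doy <- function(doy) {
  ifelse(doy >= 213L, doy - 212L, season_jan1_index() + doy - 1L)
}

## mean over a window of years; vals named or aligned with yrs
window_mean <- function(vals, yrs, window) {
  sel <- yrs >= window[1L] & yrs <= window[2L]
  if (!any(sel)) stop("window [", window[1L], ", ", window[2L],
                      "] not covered by the series")
  mean(vals[sel])
}

## centred moving average of width k (NA at the edges)
moving_average <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

## population variance (1/n normalisation); stated so tests are exact
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

## weighted population variance with normalised weights
pop_var_weighted <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sum(w * (x - m)^2)
}

#' Read a gridded long-format ensemble CSV
#'
#' Reads the layout the pipeline writes (columns `run`, `grid_id`, `lat`,
#' `lon`, `date`, `tmean`, `tmin`) and restores the `Date` class.
#'
#' @param path CSV file
#' @return long-format ensemble data frame
#' @export
read_ensemble_csv <- function(path) {
  x <- utils::read.csv(path)
  x$date <- as.Date(x$date)
  x
}
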