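## Temporal interpolation, spatial aggregation/interpolation and
## distribution-based bias correction of temperature series.

#' Interpolate daily temperature extremes to hourly values
#'
#' A cubic spline is laid through two anchor points per day - the daily
#' minimum at the sunrise hour (from the astronomical day length) and the
#' daily maximum at 14:00 - and evaluated at every hour.  A tapered
#' correction (zero at the anchor hours) then makes each day's 24 hourly
#' values average exactly to the daily mean, so the anchors are honoured
#' and the daily mean is conserved.
#'
#' @param daily data frame with columns `date`, `tmin`, `tmax`, `tmean`;
#'   days with any missing value are skipped and reported via the
#'   `skipped` attribute
#' @param latitude degrees north, for the sunrise hour
#' @return data frame `date`, `hour` (0-23), `temp`; attribute `skipped`
#'   holds the dates of dropped days
#' @export
daily_to_hourly <- function(daily, latitude = 52.5) {
  stopifnot(all(c("date", "tmin", "tmax", "tmean") %in% names(daily)))
  ok <- stats::complete.cases(daily[c("tmin", "tmax", "tmean")])
  skipped <- daily$date[!ok]
  d <- daily[ok, , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete days to interpolate")
  doy <- doy_of(d$date)
  sunrise <- 12 - compute_daylength(latitude, doy) / 2
  t0 <- as.numeric(d$date - d$date[1L]) * 24
  anchor_t <- c(t0 + sunrise, t0 + 14)
  anchor_v <- c(d$tmin, d$tmax)
  o <- order(anchor_t)
  sp <- stats::splinefun(anchor_t[o], anchor_v[o], method = "fmm")
  hours <- rep(0:23, times = nrow(d))
  ht <- rep(t0, each = 24L) + hours
  temp <- sp(ht)
  ## taper weights: zero at the two anchor hours, largest between them
  for (i in seq_len(nrow(d))) {
    idx <- ((i - 1L) * 24L + 1L):(i * 24L)
    h <- 0:23
    w <- pmin(abs(h - sunrise[i]), abs(h - 14))
    delta <- d$tmean[i] - mean(temp[idx])
    if (sum(w) > 0) temp[idx] <- temp[idx] + delta * 24 * w / sum(w)
  }
  out <- data.frame(date = rep(d$date, each = 24L), hour = hours,
                    temp = temp)
  attr(out, "skipped") <- skipped
  out
}

#' Nine-point spatial floating mean
#'
#' Replaces each grid point by the mean of itself and its up to eight
#' neighbours (3 x 3 window); edge points average over the neighbours that
#' exist.  Grid resolution is unchanged.
#'
#' @param field numeric matrix (one time step) or 3-d array
#'   `[rows, cols, time]`
#' @return object of the same shape
#' @export
spatial_floating_mean <- function(field) {
  smooth1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    padded <- matrix(0, nr + 2L, nc + 2L)
    counts <- matrix(0, nr + 2L, nc + 2L)
    padded[2:(nr + 1L), 2:(nc + 1L)] <- m
    counts[2:(nr + 1L), 2:(nc + 1L)] <- 1
    s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
    for (di in 0:2) for (dj in 0:2) {
      s <- s + padded[di + 1:nr, dj + 1:nc]
      n <- n + counts[di + 1:nr, dj + 1:nc]
    }
    s / n
  }
  if (is.matrix(field)) return(smooth1(field))
  if (length(dim(field)) == 3L) {
    out <- field
    for (k in seq_len(dim(field)[3L])) out[, , k] <- smooth1(field[, , k])
    return(out)
  }
  stop("field must be a matrix or a 3-d array")
}

#' Fit an exponential variogram by least squares
#'
#' Empirical semivariances are computed in distance bins and an
#' exponential model `gamma(d) = nugget + sill * (1 - exp(-d / range))`
#' is fitted by unweighted least squares.
#'
#' @param x,y coordinates of the samples
#' @param value sample values
#' @param n_bins number of distance bins
#' @return list with `nugget`, `sill`, `range` (class `variogram_model`)
#' @export
fit_variogram <- function(x, y, value, n_bins = 10L) {
  stopifnot(length(x) == length(y), length(x) == length(value))
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- upper.tri(d)
  dd <- d[iu]
  gg <- 0.5 * outer(value, value, "-")[iu]^2
  br <- seq(0, max(dd), length.out = n_bins + 1L)
  bin <- cut(dd, br, include.lowest = TRUE)
  emp_d <- tapply(dd, bin, mean)
  emp_g <- tapply(gg, bin, mean)
  keep <- is.finite(emp_d) & is.finite(emp_g)
  emp_d <- emp_d[keep]; emp_g <- emp_g[keep]
  obj <- function(p) {
    g <- p[1L] + p[2L] * (1 - exp(-emp_d / p[3L]))
    sum((g - emp_g)^2)
  }
  start <- c(0, max(emp_g), max(emp_d) / 3)
  fit <- stats::optim(start, obj, lower = c(0, 1e-8, 1e-6),
                      upper = c(max(emp_g) + 1e-8, 2 * max(emp_g) + 1,
                                10 * max(emp_d)),
                      method = "L-BFGS-B")
  structure(list(nugget = fit$par[1L], sill = fit$par[2L],
                 range = fit$par[3L]), class = "variogram_model")
}

variogram_eval <- function(vgm, d) {
  vgm$nugget * (d > 0) + vgm$sill * (1 - exp(-d / vgm$range))
}

#' Ordinary kriging interpolation
#'
#' Solves the ordinary-kriging system (weights constrained to sum to one)
#' for each target location.  Exact at sample locations.
#'
#' @param samples data frame with columns `x`, `y`, `value` (at least 3
#'   non-collinear points)
#' @param targets data frame with columns `x`, `y`
#' @param vgm a `variogram_model` (see [fit_variogram()]); fitted from the
#'   samples when `NULL`
#' @return numeric vector of estimates, one per target; attribute
#'   `weights` holds the weight matrix (targets x samples)
#' @export
krige_field <- function(samples, targets, vgm = NULL) {
  stopifnot(all(c("x", "y", "value") %in% names(samples)),
            all(c("x", "y") %in% names(targets)))
  n <- nrow(samples)
  if (n < 3L) stop("ordinary kriging needs at least 3 samples")
  if (is.null(vgm))
    vgm <- fit_variogram(samples$x, samples$y, samples$value)
  D <- as.matrix(stats::dist(samples[c("x", "y")]))
  A <- rbind(cbind(variogram_eval(vgm, D), 1), c(rep(1, n), 0))
  Ai <- tryCatch(solve(A), error = function(e)
    stop("singular kriging system (duplicate sample locations or ",
         "degenerate variogram): ", conditionMessage(e)))
  est <- numeric(nrow(targets))
  W <- matrix(NA_real_, nrow(targets), n)
  for (j in seq_len(nrow(targets))) {
    d0 <- sqrt((samples$x - targets$x[j])^2 + (samples$y - targets$y[j])^2)
    ## coincident target: exact interpolator
    hit <- which(d0 < 1e-12)
    if (length(hit)) {
      est[j] <- samples$value[hit[1L]]
      W[j, ] <- 0; W[j, hit[1L]] <- 1
      next
    }
    b <- c(variogram_eval(vgm, d0), 1)
    lambda <- Ai %*% b
    W[j, ] <- lambda[seq_len(n)]
    est[j] <- sum(lambda[seq_len(n)] * samples$value)
  }
  attr(est, "weights") <- W
  est
}

#' Build a quantile-mapping transfer function for one month
#'
#' Non-parametric quantile map from Gaussian-kernel-smoothed empirical
#' distributions: a simulated value `x` is mapped to the observed quantile
#' at the simulated probability level, `Qobs(Fsim(x))`.  The bandwidth `h`
#' is a fraction of the sample standard deviation (default 0.1).  Tails
#' beyond the calibration range are extrapolated linearly, since projected
#' warming exceeds the calibration quantiles.
#'
#' @param obs,sim reference and simulated values of the same calendar
#'   month (>= 30 values each)
#' @param month calendar month 1-12 the function applies to
#' @param h kernel bandwidth as a fraction of the sample sd
#' @return object of class `transfer_function`: callable mapping with
#'   fields `month`, `h`
#' @export
build_transfer_function <- function(obs, sim, month, h = 0.1) {
  stopifnot(length(obs) >= 30L, length(sim) >= 30L,
            month %in% 1:12)
  if (stats::sd(obs) < 1e-9 || stats::sd(sim) < 1e-9) {
    ## degenerate distributions: identity plus the mean shift
    shift <- mean(obs) - mean(sim)
    f <- local({
      shift <- shift
      function(x) x + shift
    })
    return(structure(list(map = f, month = month, h = h,
                          shift_only = TRUE),
                     class = "transfer_function"))
  }
  probs <- seq(0.005, 0.995, by = 0.005)
  qs <- kernel_quantiles(sim, probs, h * stats::sd(sim))
  qo <- kernel_quantiles(obs, probs, h * stats::sd(obs))
  ## enforce monotone knots (kernel CDFs are monotone; cummax guards
  ## against numerically flat stretches)
  qs <- cummax(qs); qo <- cummax(qo)
  keep <- c(TRUE, diff(qs) > 1e-9)
  qs <- qs[keep]; qo <- qo[keep]
  slope_lo <- (qo[2L] - qo[1L]) / (qs[2L] - qs[1L])
  m <- length(qs)
  slope_hi <- (qo[m] - qo[m - 1L]) / (qs[m] - qs[m - 1L])
  f <- local({
    qs <- qs; qo <- qo; slope_lo <- slope_lo; slope_hi <- slope_hi
    function(x) {
      y <- stats::approx(qs, qo, xout = x, rule = 2)$y
      lo <- x < qs[1L]; hi <- x > qs[length(qs)]
      y[lo] <- qo[1L] + slope_lo * (x[lo] - qs[1L])
      y[hi] <- qo[length(qo)] + slope_hi * (x[hi] - qs[length(qs)])
      y
    }
  })
  structure(list(map = f, month = month, h = h, shift_only = FALSE),
            class = "transfer_function")
}

## smoothed empirical quantiles: invert the Gaussian-kernel CDF
## Fhat(x) = mean(pnorm((x - X_i) / bw)) on a fine grid
kernel_quantiles <- function(x, probs, bw) {
  grid <- seq(min(x) - 4 * bw, max(x) + 4 * bw, length.out = 1024L)
  cdf <- vapply(grid, function(g) mean(stats::pnorm((g - x) / bw)),
                numeric(1L))
  stats::approx(cdf, grid, xout = probs, rule = 2, ties = "ordered")$y
}

#' Apply monthly quantile-mapping bias correction
#'
#' @param sim data frame with `date` and one or more temperature columns
#' @param tfs list of [build_transfer_function()] objects covering every
#'   calendar month present in `sim`
#' @param cols columns of `sim` to correct
#' @return `sim` with the selected columns mapped through their month's
#'   transfer function; the calendar is unchanged
#' @export
apply_bias_correction <- function(sim, tfs, cols = "tmean") {
  months_present <- unique(as.integer(format(sim$date, "%m")))
  tf_months <- vapply(tfs, function(tf) tf$month, numeric(1L))
  miss <- setdiff(months_present, tf_months)
  if (length(miss))
    stop("no transfer function for month(s): ", paste(miss, collapse = ", "))
  mo <- as.integer(format(sim$date, "%m"))
  out <- sim
  for (m in months_present) {
    tf <- tfs[[which(tf_months == m)[1L]]]
    sel <- mo == m
    for (cl in cols) out[[cl]][sel] <- tf$map(sim[[cl]][sel])
  }
  out
}

#' Temperature anomaly between two windows
#'
#' Mean over the target window minus mean over the reference window
#' (default reference 1971-2000).
#'
#' @param series data frame with `date` and a value column
#' @param target integer `c(first, last)` years of the target window
#' @param reference integer `c(first, last)` years of the reference window
#' @param col value column name
#' @return the anomaly (K)
#' @export
temperature_anomaly <- function(series, target, reference = c(1971, 2000),
                                col = "tmean") {
  yrs <- as.integer(format(series$date, "%Y"))
  check_window <- function(w) {
    if (!all(w[1L]:w[2L] %in% yrs))
      stop("window ", w[1L], "-", w[2L], " not fully covered")
  }
  check_window(reference); check_window(target)
  window_mean(series[[col]], yrs, target) -
    window_mean(series[[col]], yrs, reference)
}
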