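# Shared fixture builders and independent brute-force oracles.

# one phenological year of daily dates (Aug 1, 2000 - Jul 31, 2001; 365 d)
season_dates <- function() {
  seq.Date(as.Date("2000-08-01"), as.Date("2001-07-31"), by = "day")
}

# a season data frame from a temperature vector (recycled)
make_season <- function(tmean) {
  d <- season_dates()
  data.frame(date = d, tmean = rep_len(tmean, length(d)))
}

# calendar DOY of a season index in the fixture season (1 = Aug 1, 2000)
doy_of_season_index <- function(i) {
  as.integer(format(season_dates()[i], "%j"))
}

# small ensemble for projection tests
tiny_ensemble <- function(n_runs = 1, n_grid = 1, years = c(1995, 2000),
                          seed = 1, ...) {
  gen_climate_ensemble(scenario_config(n_runs = n_runs, n_grid = n_grid,
                                       years = years, seed = seed, ...))
}

# brute-force blossom frost risk: explicit double loop over years and days
# (calendar fields extracted up front, day-level logic spelled out)
theta_bruteforce <- function(bloom, tmin_df, beta, window) {
  yrs <- window[1]:window[2]
  row_year <- as.integer(format(tmin_df$date, "%Y"))
  row_doy <- as.integer(format(tmin_df$date, "%j"))
  hits <- 0
  for (y in yrs) {
    bd <- bloom$doy[bloom$year == y]
    if (length(bd) == 0 || is.na(bd)) next
    frosty <- FALSE
    for (i in which(row_year == y)) {
      if (row_doy[i] >= bd && row_doy[i] <= 212 &&
            tmin_df$tmin[i] <= beta) frosty <- TRUE
    }
    if (frosty) hits <- hits + 1
  }
  hits / length(yrs)
}

# brute-force 3x3 floating mean by explicit neighbour loop
floating_mean_bruteforce <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0; n <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m)) {
        acc <- acc + m[ii, jj]; n <- n + 1
      }
    }
    out[i, j] <- acc / n
  }
  out
}

# independent ordinary-kriging solution by Lagrange block elimination:
# w = G^-1 (g0 - mu 1),  mu = (1' G^-1 g0 - 1) / (1' G^-1 1)
krige_bruteforce <- function(samples, targets, vgm) {
  gam <- function(d) vgm$nugget * (d > 0) + vgm$sill * (1 - exp(-d / vgm$range))
  n <- nrow(samples)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt((samples$x[i] - samples$x[j])^2 +
                (samples$y[i] - samples$y[j])^2)
    G[i, j] <- gam(d)
  }
  Ginv <- solve(G)
  ones <- rep(1, n)
  est <- numeric(nrow(targets))
  for (k in seq_len(nrow(targets))) {
    d0 <- sqrt((samples$x - targets$x[k])^2 + (samples$y - targets$y[k])^2)
    g0 <- gam(d0)
    mu <- (sum(ones * (Ginv %*% g0)) - 1) / sum(ones * (Ginv %*% ones))
    w <- Ginv %*% (g0 - mu * ones)
    est[k] <- sum(w * samples$value)
  }
  est
}

# direct Cox-Lewis statistic recomputation
cox_lewis_bruteforce <- function(event_years, period) {
  L <- period[2] - period[1] + 1
  t <- event_years - period[1] + 0.5
  n <- length(t)
  (mean(t) - L / 2) / (L / sqrt(12 * n))
}
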