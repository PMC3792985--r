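make_daily <- function(tmin, tmax, tmean, start = "2001-04-01") {
  n <- max(length(tmin), length(tmax), length(tmean))
  data.frame(date = seq.Date(as.Date(start), by = "day", length.out = n),
             tmin = rep_len(tmin, n), tmax = rep_len(tmax, n),
             tmean = rep_len(tmean, n))
}

test_that("hourly interpolation honours anchors and conserves the mean", {
  # constant input stays constant
  d <- make_daily(rep(5, 4), 5, 5)
  h <- daily_to_hourly(d)
  expect_equal(h$temp, rep(5, 96))

  # a day with tmin below zero has at least one freezing hour
  d2 <- make_daily(c(2, -3, 1), c(8, 6, 9), c(5, 1.5, 5))
  h2 <- daily_to_hourly(d2)
  day2 <- h2$temp[h2$date == d2$date[2]]
  expect_true(any(day2 <= 0))

  # daily mean is conserved
  for (dt in unique(h2$date))
    expect_equal(mean(h2$temp[h2$date == dt]),
                 d2$tmean[d2$date == dt], tolerance = 1e-9)

  # missing day is skipped and flagged
  d3 <- make_daily(c(2, NA, 1), c(8, 6, 9), c(5, 1.5, 5))
  h3 <- daily_to_hourly(d3)
  expect_equal(attr(h3, "skipped"), d3$date[2])
  expect_false(d3$date[2] %in% h3$date)
})

test_that("round-trip of a diurnal sinusoid stays within 0.6 K MAE", {
  dates <- seq.Date(as.Date("2001-05-01"), by = "day", length.out = 20)
  hours <- 0:23
  truth <- data.frame()
  for (i in seq_along(dates)) {
    base <- 10 + 3 * sin(2 * pi * i / 20)
    temp <- base + 5 * sin(2 * pi * (hours - 9.5) / 24)  # min ~ 03:30
    truth <- rbind(truth, data.frame(date = dates[i], hour = hours,
                                     temp = temp))
  }
  daily <- do.call(rbind, lapply(split(truth, truth$date), function(d)
    data.frame(date = d$date[1], tmin = min(d$temp), tmax = max(d$temp),
               tmean = mean(d$temp))))
  rebuilt <- daily_to_hourly(daily)
  interior <- truth$date %in% dates[3:18]
  mae <- mean(abs(rebuilt$temp[interior] - truth$temp[interior]))
  expect_lt(mae, 0.6)
})

test_that("floating mean matches the brute-force 9-point oracle", {
  expect_equal(spatial_floating_mean(matrix(3, 4, 5)), matrix(3, 4, 5))
  m <- matrix(0, 5, 5); m[3, 3] <- 9
  expect_equal(spatial_floating_mean(m)[3, 3], 1)
  set.seed(1)
  for (k in 1:20) {
    m <- matrix(rnorm(42), 6, 7)
    expect_equal(spatial_floating_mean(m), floating_mean_bruteforce(m))
  }
  # 3-d array form applies per time step
  a <- array(rnorm(60), c(4, 5, 3))
  sm <- spatial_floating_mean(a)
  expect_equal(sm[, , 2], floating_mean_bruteforce(a[, , 2]))
})

test_that("ordinary kriging is exact, unbiased and matches the oracle", {
  set.seed(7)
  samp <- data.frame(x = runif(10), y = runif(10), value = rnorm(10))
  vgm <- structure(list(nugget = 0.05, sill = 1, range = 0.5),
                   class = "variogram_model")
  # exact at a sample location
  est <- krige_field(samp, samp[3, c("x", "y")], vgm)
  expect_equal(as.numeric(est), samp$value[3])
  # constant field reproduced everywhere (unbiasedness constraint)
  cs <- samp; cs$value <- 7
  tg <- data.frame(x = runif(5), y = runif(5))
  expect_equal(as.numeric(krige_field(cs, tg, vgm)), rep(7, 5),
               tolerance = 1e-8)
  # weights sum to one
  est2 <- krige_field(samp, tg, vgm)
  expect_equal(rowSums(attr(est2, "weights")), rep(1, 5),
               tolerance = 1e-8)
  # independent Lagrange-elimination oracle
  expect_equal(as.numeric(est2), krige_bruteforce(samp, tg, vgm),
               tolerance = 1e-8)
  # degenerate systems fail loudly
  dup <- samp[c(1, 1, 1), ]
  expect_error(krige_field(dup, tg, vgm), "singular|at least 3")
})

test_that("variogram fitting recovers a location-free structure", {
  set.seed(3)
  s <- data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10))
  s$value <- sin(s$x / 2) + rnorm(40, sd = 0.1)
  v <- fit_variogram(s$x, s$y, s$value)
  expect_gt(v$sill, 0)
  expect_gt(v$range, 0)
  expect_gte(v$nugget, 0)
})

test_that("quantile mapping is monotone and recovers shifts", {
  set.seed(11)
  obs <- rnorm(1e4, 8, 3)
  # identical distributions: map ~ identity
  sim <- rnorm(1e4, 8, 3)
  tf <- build_transfer_function(obs, sim, month = 4)
  x <- seq(2, 14, by = 0.25)
  expect_lt(max(abs(tf$map(x) - x)), 0.2)
  # pure +2 K bias removed across central quantiles
  tf2 <- build_transfer_function(obs, obs + 2, month = 4)
  expect_lt(max(abs(tf2$map(x + 2) - x)), 0.1)
  # monotone over a wide domain including the extrapolated tails
  wide <- seq(-15, 30, by = 0.1)
  expect_true(all(diff(tf$map(wide)) >= 0))
  expect_true(all(diff(tf2$map(wide)) >= 0))
  # degenerate constant distributions: identity plus shift
  tf3 <- build_transfer_function(rep(4, 40), rep(6, 40), month = 1)
  expect_equal(tf3$map(c(6, 10)), c(4, 8))
})

test_that("bias correction maps per month and preserves order", {
  ens <- tiny_ensemble(years = c(1971, 2000), seed = 13)
  cold <- ens
  cold$tmean <- cold$tmean - 2
  mo <- as.integer(format(ens$date, "%m"))
  tfs <- lapply(1:12, function(m)
    build_transfer_function(ens$tmean[mo == m], cold$tmean[mo == m], m))
  # identity functions leave the series untouched
  id_tfs <- lapply(1:12, function(m)
    structure(list(map = identity, month = m, h = 0.1),
              class = "transfer_function"))
  expect_equal(apply_bias_correction(cold, id_tfs)$tmean, cold$tmean)
  corr <- apply_bias_correction(cold, tfs)
  # monthly means restored to the reference within 0.05 K
  for (m in 1:12)
    expect_lt(abs(mean(corr$tmean[mo == m]) - mean(ens$tmean[mo == m])),
              0.05)
  # order within a month preserved
  sel <- mo == 4
  expect_equal(rank(corr$tmean[sel]), rank(cold$tmean[sel]))
  # missing month's function is an error
  expect_error(apply_bias_correction(cold, tfs[1:11]), "month")
})

test_that("temperature anomaly has its closed forms", {
  ens <- tiny_ensemble(years = c(1971, 2000), seed = 19,
                       warming_per_century = 0)
  expect_equal(temperature_anomaly(ens, c(1971, 2000), c(1971, 2000)), 0)
  expect_error(temperature_anomaly(ens, c(2001, 2030), c(1971, 2000)),
               "covered")
  # linear trend, window centres 100 years apart
  tr <- gen_climate_ensemble(scenario_config(
    n_runs = 1, n_grid = 1, years = c(1951, 2100), noise_sd = 0,
    tmin_noise_sd = 0, warming_per_century = 3, run_bias = 0, seed = 1))
  expect_equal(temperature_anomaly(tr, c(2071, 2100), c(1971, 2000)), 3,
               tolerance = 0.02)
})
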