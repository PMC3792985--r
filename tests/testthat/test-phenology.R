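test_that("day length behaves at the equator, equinox and solstice", {
  expect_true(all(abs(compute_daylength(0, 1:365) - 12) < 0.2))
  for (lat in c(-40, 10, 52.5)) # vernal equinox ~ doy 80
    expect_lt(abs(compute_daylength(lat, 80) - 12), 0.3)
  expect_error(compute_daylength(70, 100), "polar")

  # brute-force oracle: fraction of the day with solar elevation > 0,
  # using an independent declination (Spencer Fourier series)
  elev_daylength <- function(lat, doy) {
    g <- 2 * pi * (doy - 1) / 365
    decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
    h <- seq(0, 2 * pi, length.out = 20001)  # hour angle over the day
    phi <- lat * pi / 180
    elev <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h)
    24 * mean(elev > 0)
  }
  for (doy in c(21, 80, 172, 300))
    expect_lt(abs(compute_daylength(52.5, doy) -
                    elev_daylength(52.5, doy)), 0.2)
})

test_that("chill rate implements the chill-day band and Utah weights", {
  p <- pheno_params(2, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400, b = -0.01)
  expect_equal(chill_rate(2, c(-0.1, 0, 3, 7, 7.1), p),
               c(0, 1, 1, 1, 0))
  expect_error(chill_rate(1, 5, default_pheno_params(1)), "chilling")
  expect_error(chill_rate(5, 5, default_pheno_params(5)), "chilling")

  # hand-summed Utah weights across all bands
  p4 <- default_pheno_params(4)
  temps <- c(-2, 1.0, 2.0, 5.0, 10.0, 13.0, 17.0, 25.0)
  hand <- 0 + 0 + 0.5 + 1 + 0.5 + 0 + (-0.5) + (-1)
  expect_equal(sum(chill_rate(4, temps, p4)), hand)
})

test_that("forcing rate is over-threshold GDD with a photoperiod factor", {
  p2 <- default_pheno_params(2)
  expect_equal(force_rate(2, c(2, 4, 6), 10, p2), c(0, 0, 2))
  p6 <- pheno_params(6, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400, b = -0.01,
                     c = 1)
  # c = 1, T = Tbf + 2, D = 18 -> 2 * 1.5 = 3
  expect_equal(force_rate(6, 6, 18, p6), 3)
  # D = 12 h is the reference photoperiod: factor exactly 1
  expect_equal(force_rate(6, 6, 12, p6), force_rate(2, 6, 12, p2))
  # c = 0 collapses to the base rate for any D
  p6c0 <- pheno_params(6, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400,
                       b = -0.01, c = 0)
  expect_equal(force_rate(6, 6, 18, p6c0), 2)
})

test_that("parameter sets enforce the per-model field pattern and bounds", {
  expect_error(pheno_params(2, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400),
               "requires")
  expect_error(pheno_params(1, Tbf = 4, Fcrit = 100, Tbc = 5),
               "does not use")
  expect_error(pheno_params(1, Tbf = 12, Fcrit = 100), "Tbf")
  expect_error(pheno_params(5, Tbf = 4, Fcrit = 100, c = -1, t1 = 1), "c")
})

test_that("constant forcing gives an arithmetic bloom date (model 1)", {
  p <- pheno_params(1, Tbf = 5, Fcrit = 50)
  season <- make_season(10)  # rate 5/day from Jan 1
  r <- run_season(1, p, season)
  expect_equal(r$t2, 10)  # 10th forcing day = Jan 10, DOY 10
  expect_false(r$unfulfilled)
  expect_equal(r$t1, 1)
})

test_that("a winter with no chill-band exposure leaves chilling unfulfilled", {
  p <- default_pheno_params(2)
  r <- run_season(2, p, make_season(20))
  expect_true(r$unfulfilled)
  expect_true(is.na(r$t2))
})

test_that("sequential accumulation matches a hand-stepped trace", {
  # 90-day chill block at 5 deg C starting Aug 1, then constant 12 deg C
  p <- pheno_params(2, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400, b = -0.01)
  tm <- c(rep(5, 90), rep(12, 275))
  r <- run_season(2, p, make_season(tm))
  # chilling: 1 unit/day from day 1 -> Sc hits 70 on season day 70
  expect_equal(r$t1_index, 70L)
  # Sc(t1) = 70 -> Fcrit = 400 * exp(-0.7); forcing 1/day (5-4) until day
  # 90, then 8/day; hand-stepped completion:
  fcrit <- 400 * exp(-0.7)
  acc <- cumsum(c(rep(1, 21), rep(8, 275)))  # days 70..90 at 5 deg C
  hand_days <- which(acc >= fcrit)[1]
  expect_equal(r$t2_index, 70L + hand_days - 1L)
  expect_equal(r$t2, doy_of_season_index(r$t2_index))
})

test_that("model nesting: c = 0 variants reproduce their base models", {
  set.seed(42)
  for (k in 1:10) {
    ens <- tiny_ensemble(years = c(1996, 2001), seed = 100 + k)
    # model 6 vs 2 and 7 vs 3
    for (pair in list(c(6, 2), c(7, 3))) {
      pe <- pheno_params(pair[1], Tbf = 4, Tbc = 7, Ccrit = 70, a = 400,
                         b = -0.01, c = 0)
      pb <- pheno_params(pair[2], Tbf = 4, Tbc = 7, Ccrit = 70, a = 400,
                         b = -0.01)
      re <- run_seasons(pair[1], pe, ens)
      rb <- run_seasons(pair[2], pb, ens)
      expect_identical(re$t2, rb$t2)
      expect_identical(re$t1, rb$t1)
    }
    # model 5 with c = 0 and t1 = Jan 1 vs model 1
    p5 <- pheno_params(5, Tbf = 5, Fcrit = 145, c = 0, t1 = 1)
    p1 <- pheno_params(1, Tbf = 5, Fcrit = 145)
    expect_identical(run_seasons(5, p5, ens)$t2,
                     run_seasons(1, p1, ens)$t2)
  }
})

test_that("warming the forcing phase never delays bloom", {
  ens <- tiny_ensemble(years = c(1994, 2000), seed = 17)
  seasons <- split_seasons(ens)
  # sequential/thermal models: warm every day from the baseline chilling
  # completion onward (chilling already satisfied there)
  for (m in c(1, 2, 4, 5, 6)) {
    p <- default_pheno_params(m)
    for (s in seasons) {
      base <- run_season(m, p, s)
      if (is.na(base$t1_index)) next
      warm <- s
      idx <- seq(base$t1_index, nrow(s))
      warm$tmean[idx] <- warm$tmean[idx] + 1.5
      shifted <- run_season(m, p, warm)
      expect_false(shifted$unfulfilled)
      expect_lte(shifted$t2_index, base$t2_index)
    }
  }
  # parallel models: warm only days already above the chill band, so the
  # chilling path (and hence gate and threshold) is unchanged
  for (m in c(3, 7)) {
    p <- default_pheno_params(m)
    base <- run_seasons(m, p, ens)
    warm <- ens
    hot <- warm$tmean > p$Tbc
    warm$tmean[hot] <- warm$tmean[hot] + 1.5
    shifted <- run_seasons(m, p, warm)
    ok <- !base$unfulfilled & !shifted$unfulfilled
    expect_true(all(shifted$t2_index[ok] <= base$t2_index[ok]),
                info = paste("model", m))
  }
})

test_that("reduced winter chill exposure weakly delays dormancy release", {
  ens <- tiny_ensemble(years = c(1994, 2000), seed = 23)
  for (m in c(2, 3, 4, 6, 7)) {
    p <- default_pheno_params(m)
    base <- run_seasons(m, p, ens)
    reduced <- ens
    # push November out of every chill band (weight 0 for Utah too)
    mo <- as.integer(format(reduced$date, "%m"))
    reduced$tmean[mo == 11] <- 15
    shifted <- run_seasons(m, p, reduced)
    ok <- !is.na(base$t1_index) & !is.na(shifted$t1_index)
    expect_true(all(shifted$t1_index[ok] >= base$t1_index[ok]),
                info = paste("model", m))
  }
})

test_that("hourly Utah chilling plugs into the model-4 season", {
  season <- make_season(rep(c(5, 12), c(120, 245)))
  p <- default_pheno_params(4)
  # constant days: hourly aggregation equals the daily weight exactly
  hourly <- data.frame(date = rep(season$date, each = 24),
                       temp = rep(season$tmean, each = 24))
  ch <- utah_chill_from_hourly(hourly)
  expect_equal(nrow(ch), nrow(season))
  expect_equal(ch$chill,
               chill_rate(4, season$tmean, p))
  r_daily <- run_season(4, p, season)
  r_hourly <- run_season(4, p, season, chill_daily = ch$chill)
  expect_equal(r_hourly$t2, r_daily$t2)
  # a diurnal cycle spanning several weight bands differs from the
  # daily-mean weight
  hourly$temp <- hourly$temp + rep(6 * sin(2 * pi * (0:23 - 9) / 24),
                                   nrow(season))
  ch2 <- utah_chill_from_hourly(hourly)
  expect_false(isTRUE(all.equal(ch2$chill,
                                chill_rate(4, season$tmean, p))))
  expect_error(run_season(2, default_pheno_params(2), season,
                          chill_daily = ch$chill), "model 4")
})

test_that("seasons shorter than a year are rejected", {
  s <- make_season(10)[1:200, ]
  expect_error(run_season(1, default_pheno_params(1), s), "full")
})
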