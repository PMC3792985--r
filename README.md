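# bloomrisk

Projection of apple (*Malus domestica*) bloom dates and blossom frost
risk from ensembles of regional-climate-model temperature series, with
explicit separation of climate-model and impact-model uncertainty.

## The problem

Spring frosts during or after flowering are a major production risk for
apple. Whether climate warming raises or lowers that risk depends on a
race between two moving dates: the bloom day, driven by winter chilling
and spring forcing, and the last spring freeze. Any projection of the
outcome chains several models together — emission scenario, climate
model run, bias correction, phenological model — and each link adds
variance. `bloomrisk` implements the full chain and asks not only *what*
changes, but *when* the projected change exceeds the noise of the
projection (the time of emergence).

## What the package computes

**Phenological models.** Seven daily chilling/forcing models, addressed
by integer id:

| id | type | chilling | day length |
|----|------|----------|------------|
| 1 | thermal time (forcing from Jan 1) | – | – |
| 2 | sequential chilling–forcing | chill days | – |
| 3 | parallel chilling–forcing | chill days | – |
| 4 | modified Utah + fixed forcing threshold | Utah weights | – |
| 5 | thermal time, forcing from calibrated start | – | yes |
| 6 | model 2 with day-length factor | chill days | yes |
| 7 | model 3 with day-length factor | chill days | yes |

All models accumulate the forcing rate
`Rf = max(T − Tbf, 0) · (D / 12 h)^c` (with `c = 0` for models 1–4);
chill-day models count days with `0 °C ≤ T ≤ Tbc`, the effective range
for apple development. Sequential models finish chilling at `Sc ≥ Ccrit`
(day `t1`) and bloom (day `t2`) once the forcing state reaches
`Fcrit = a·exp(b·Sc(t1))`; parallel models accumulate both states
concurrently, with forcing gated by the chilling fraction
`min(Sc/Ccrit, 1)`. Seasons that never complete chilling or bloom are
flagged as *unfulfilled*.

**Calibration.** `pheno_fit()` fits a model to observed bloom days of
year by bound-constrained simulated annealing (base temperatures
searched in 0–10 °C), minimising the RMSE between observed and simulated
DOY; `loo_prmse()` and `external_prmse()` give leave-one-out and
held-out-location prediction errors.

**Climate preparation.** Daily→hourly cubic-spline interpolation
anchored at sunrise (Tmin) and 14:00 (Tmax), nine-point spatial floating
means, ordinary kriging with a least-squares exponential variogram, and
monthly distribution-based quantile-mapping bias correction built from
Gaussian-kernel-smoothed CDFs (bandwidth 0.1 sd).

**Risk statistics.** The blossom frost risk
`θ = (# years with min Tmin in [t2, Jul 31] ≤ β) / 30`
per 30-year window and threshold `β` (0 or 2 °C), its change `Δθ`,
last-spring-freeze extraction, unfulfilled-chilling fractions, and
Gaussian-kernel densities of `Δθ` samples.

**Uncertainty partition.** Per (run, model) area-mean change series are
smoothed (10-year moving average), fitted with a 4th-order polynomial,
and their variance split into internal variability `V`, climate-run
variance `M(t)` and impact-model variance `I(t)`. With the
error-weighted mean signal `G(t)`, the fractional uncertainty
`F(t) = λ·sqrt(V + M + I) / |G|` yields the time of emergence
(first year with `F ≤ 1`, sustained).

**Trend tests.** Mann–Kendall (tie-corrected, continuity-corrected) for
continuous series and the Cox–Lewis statistic
`U = (mean event time − L/2)/(L/sqrt(12 n))` for frost-event series.

A seeded synthetic generator (`scenario_config()`,
`gen_climate_ensemble()`, `gen_bloom_observations()`) produces warming
climate ensembles — seasonal cycle, linear trend, run bias, AR(1)
weather noise — and bloom observations from a known model, so the whole
chain is testable without external climate archives.

## Worked example

```r
library(bloomrisk)

cfg   <- scenario_config(n_runs = 1, n_grid = 1, years = c(1969, 2000),
                         seed = 42)
temps <- gen_climate_ensemble(cfg)
obs   <- gen_bloom_observations(2, default_pheno_params(2), temps,
                                obs_noise_sd = 2, seed = 7)

fit <- pheno_fit(2, obs, temps, sa_control = list(seed = 1))
print(fit)
#> Calibrated phenological model (simulated annealing)
#> Phenological model 2 (sequential chilling-forcing)
#>   Tbf = 4.6514
#>   Tbc = 6.8875
#>   Ccrit = 40.816
#>   a = 582.7
#>   b = -0.028856
#>   RMSE = 2.22 d over 31 seasons

pred  <- predict(fit, temps)
theta <- frost_risk_theta(pred, temps[, c("date", "tmin")], beta = 0,
                          window = c(1971, 2000))
theta
#> [1] 0.03333333

mann_kendall(pred$doy)
#> Mann-Kendall test: statistic = -87  p = 0.143  n = 31
```

The fit recovers the forcing base temperature (truth 4 °C) within
0.7 °C and reaches a 2.2-day RMSE against observations carrying 2 days
of noise; note that `Ccrit`, `a` and `b` trade off against each other,
so individual chilling parameters are less identifiable than the
predicted bloom dates. One year in thirty has a freeze at or below 0 °C
after the predicted bloom day (θ = 0.033), and this stationary
1969–2000 slice shows no significant bloom trend (p = 0.14).

`run_pipeline(default_pipeline_config())` executes the whole chain —
generation, bias correction, calibration, ensemble projection, risk
statistics, uncertainty partition, trend masks — and writes plain-text
artifacts plus a run log; `write_report()` condenses them into summary
tables.

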