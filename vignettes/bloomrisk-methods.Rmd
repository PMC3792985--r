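---
title: "Projecting apple bloom and blossom frost risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting apple bloom and blossom frost risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomrisk)
```

This vignette documents the scientific choices inside `bloomrisk`: the
phenological model family, the calibration and risk statistics, the
uncertainty decomposition, what the synthetic generator does and does
not emulate, and the numerical decisions a user may want to audit.

## The phenological model family

All seven models share two ingredients. The *forcing* rate is the
over-threshold growing-degree rate, optionally damped or boosted by the
photoperiod:

$$R_f(T, D) = \max(T - T_{bf},\, 0) \cdot (D / 12\,\mathrm{h})^c ,$$

with the day length $D$ from the astronomical sunrise/sunset geometry
at the site latitude and $c \ge 0$ ($c = 0$, i.e. factor 1, for models
1–4). Twelve hours is the natural reference photoperiod: the factor is
exactly one at the equinoxes, below one in winter and above one in late
spring. The *chilling* rate of models 2, 3, 6 and 7 is a chill day,
$R_c = \mathbf{1}\{0\,^\circ\mathrm{C} \le T \le T_{bc}\}$; 0–10 °C is
treated as the effective temperature range for apple development, and
both base temperatures are calibrated inside it. Model 4 replaces chill
days by the classical stepwise Utah weights
(0 / 0.5 / 1 / 0.5 / 0 / −0.5 / −1 over the bands delimited by 1.4,
2.4, 9.1, 12.4, 15.9 and 18 °C), with the chilling state floored at
zero so warm spells cannot drive it negative. Utah chilling is
classically evaluated hourly; at the package's canonical daily
resolution the weights are applied to daily means, which compresses the
diurnal range through the bands — one reason model 4's absolute chill
unit numbers should not be compared against orchard-management tables.

A season is the *phenological year*, August 1 through July 31, so one
chilling and the following forcing phase always fall in the same
season. The model structures are:

* **Model 1** accumulates forcing from a fixed January 1 start and
  blooms at $S_f \ge F_{crit}$. It implicitly assumes dormancy is
  always satisfied — the structural weakness that motivates the
  chilling models.
* **Model 5** starts forcing at a *calibrated* day $t_1$ (any day from
  August 1) and applies the day-length factor.
* **Sequential models (2, 6)** accumulate chilling from August 1 until
  $S_c \ge C_{crit}$ (completion day $t_1$), then forcing, with the
  requirement tied to the attained chilling state through
  $F_{crit} = a\,e^{b S_c(t_1)}$ (with $b \le 0$: more chill, less
  forcing needed).
* **Parallel models (3, 7)** accumulate both states concurrently from
  August 1. Forcing is gated by the chilling fraction
  $\min(S_c/C_{crit}, 1)$ and bloom occurs at the first day — at or
  after chilling completion — where the gated forcing state exceeds
  $a\,e^{b S_c(t)}$. Requiring $t_2 \ge t_1$ resolves the coupling
  ambiguity of the parallel family in favour of the biologically
  interpretable ordering (dormancy release precedes bloom); without it,
  degenerate parameter sets could "bloom" in autumn through the partial
  gate.
* **Model 4** runs Utah chilling to $C_{crit}$, then forcing against a
  fixed $F_{crit}$.

A season with incomplete chilling or no bloom by July 31 is flagged
*unfulfilled*; July 31 (DOY 212) is the universal season end, so a
hypothetical later bloom counts as no bloom. Unfulfilled seasons stay
in every denominator downstream (they are data, not gaps).

The family nests: model 6 with $c = 0$ *is* model 2, model 7 is model
3, and model 5 with $c = 0$ and $t_1$ = January 1 is model 1. The test
suite asserts these identities exactly, which pins down the day-length
factor as a pure multiplier on the forcing rate (it does not touch
chilling: radiation is assumed to matter only during forcing).

## Calibration

`pheno_fit()` minimises the RMSE between observed and simulated bloom
DOY with bound-constrained simulated annealing: Gaussian proposals
scaled to the box width, reflected into the bounds, geometric cooling
from an initial temperature of 20 (objective units, days) down to 0.01,
4000 iterations per chain and two independently started chains by
default. The objective over a candidate parameter set charges seasons
where the candidate produces *no* bloom a fixed 100-day error — this
keeps the objective finite and makes degenerate corners of the box
(e.g. unreachable chilling thresholds) steeply unattractive without
discarding data. Ties between equal objectives resolve to the first
one found under the seeded schedule, so a fit is reproducible from its
seed.

The annealing budget is a compromise: with ~30 seasons an objective
evaluation costs ~2 ms, a default fit ~15 s. Parameter recovery
experiments (30 seasons, 2 days of observation noise) recover the
forcing base temperature to well within ±1.5 °C for every model.
Individual chilling parameters ($C_{crit}$, $a$, $b$) are only weakly
identified — they trade off along a ridge of nearly identical bloom
series — which is the expected behaviour of this model family, not a
defect of the optimiser; validation should always be read off
predicted dates (RMSE, PRMSE), not off individual parameter values.
`loo_prmse()` implements full leave-one-out cross-validation (each
fold refits with a fold-specific seed); `external_prmse()` pools
squared errors at held-out locations.

## Climate preparation

*Temporal interpolation.* The daily→hourly scheme lays a single cubic
spline through two anchors per day — the daily minimum at the
astronomical sunrise hour, the maximum at 14:00 — and evaluates it
hourly. A tapered correction, zero at the anchor hours and largest
between them, then forces each day's 24 values to average exactly to
the daily mean. On a synthetic diurnal sinusoid the round trip stays
below 0.6 K mean absolute error. The anchor choice (sunrise from day
length, mid-afternoon maximum) is the standard parameterisation of the
diurnal cycle; it is a stand-in for more elaborate published schemes
and is deliberately simple.

*Spatial operations.* The nine-point floating mean replaces each grid
point by the mean of its 3×3 neighbourhood (shrinking at the edges),
preserving grid resolution while damping grid-scale noise. Ordinary
kriging solves the standard augmented system with weights summing to
one; the variogram defaults to an exponential model
$\gamma(d) = n + s(1 - e^{-d/r})$ fitted by least squares to binned
empirical semivariances. Kriging is exact at sample locations, and the
implementation is cross-checked in the tests against an independent
Lagrange-elimination solution of the same equations.

*Bias correction.* Simulated series are corrected month by month
through non-parametric quantile maps $x \mapsto Q_{obs}(F_{sim}(x))$,
with both CDFs smoothed by a Gaussian kernel of bandwidth 0.1 sample
standard deviations. Tails beyond the calibration range extrapolate
linearly with the boundary slope — necessary because projected warming
exceeds every calibrated quantile. Quantile maps are monotone, so the
correction never reorders values within a month. Daily means and daily
minima are corrected separately: frost counting depends on the Tmin
distribution, which is precisely what raw climate-model output tends
to get wrong. On a synthetic ensemble with a −2 K cold bias the
correction removes more than 80% of the April frost-day count error.

## Risk statistics

The blossom frost risk of a 30-year window is
$$\theta = \frac{\#\{\text{years: } \min_{t \in [t_2,\,212]} T_{min}(t) \le \beta\}}{30},$$
with the search interval closed on both ends (a frost on the bloom day
counts) and $\beta = 0$ °C (freeze) or 2 °C (possible damage through
radiative cooling of tissue below air temperature). Years without
bloom cannot incur blossom frost: they are excluded from the numerator
but kept in the fixed denominator of 30, so unfulfilled chilling
lowers $\theta$ rather than silently shrinking the sample. Windows
shorter than 30 years are rejected unless a proportional denominator
is requested explicitly. $\theta$ is therefore a multiple of 1/30, and
$\Delta\theta$ between windows lies in [−1, 1]. Distributions of
$\Delta\theta$ across grid points, runs and models are summarised by a
Gaussian-kernel density with a bandwidth floor of 0.005 (half a
percentage point) to keep degenerate samples finite.

## Uncertainty partition and time of emergence

Annual area-mean change series (relative to the 1971–2000 mean) per
(run, model) are smoothed with a 10-year centred moving average and
approximated by a 4th-order polynomial. Three components are formed at
each year:

* $V$ — internal variability: residual variance about the polynomial
  trends, pooled over members and held constant in time;
* $M(t)$ — climate-run variance: the (weighted) mean over impact
  models of the across-run population variance of the trend fits;
* $I(t)$ — impact-model variance: the weighted population variance
  across models of the run-mean fits.

Fractions $V/T$, $M/T$, $I/T$ with $T = V + M + I$ sum to one at every
time step by construction (asserted to $10^{-12}$ in the tests).
Impact models are weighted inversely to their error (e.g. PRMSE), with
an error floor of 0.1 days preventing an infinite weight; population
(1/n) normalisation is used throughout so the small-ensemble algebra
is exact. The weighted mean change $G(t)$ and the fractional
uncertainty $F(t) = \lambda\sqrt{T(t)}/|G(t)|$ — the inverse
signal-to-noise ratio at confidence multiplier $\lambda$ (0.674, 1,
1.645 for the 50, 68.3 and 90% levels) — give the *time of emergence*:
the first year after the reference epoch at which $F \le 1$ and stays
there for at least five consecutive years. The persistence rule
suppresses single-year dips of a noisy $F$; the reported range of
emergence years in ensemble studies implies some such stabilisation,
and five years is the package's choice. The year of minimum $F$ is
reported alongside. On constructed ensembles with linear signal
$k\,t$ and constant across-run spread $\sigma$, the implementation
recovers the analytic emergence time $\lambda\sigma/k$ to within one
year.

## Trend tests

Continuous series (dormancy release, bloom, last spring freeze) use
the Mann–Kendall test with tie-corrected variance and continuity
correction; event series (blossom-frost years) use the Cox–Lewis
statistic $U = (\bar{t} - L/2)/(L/\sqrt{12 n})$, standard normal under
a homogeneous event process, with event times at year midpoints
relative to the period start (the origin choice is immaterial: both
tests are invariant under time-origin shifts, and the suite checks
their empirical size stays in [0.03, 0.07] at $\alpha = 0.05$). All
p-values are two-sided. No serial-correlation correction is applied to
Mann–Kendall; for strongly autocorrelated inputs the test will be
anti-conservative.

## The synthetic generator: what it emulates, what it does not

`gen_climate_ensemble()` builds daily means as
seasonal sinusoid + linear trend + run bias + AR(1) noise, and daily
minima as the mean minus half the diurnal range plus independent
noise, clamped to never exceed the mean. Defaults describe a
north-German scenario: annual mean 9 °C, half-amplitude 8.5 K (January
≈ 0.5 °C, July ≈ 17.5 °C), +3 K per century over 1951–2100,
$\phi = 0.7$ daily autocorrelation with 2 K innovations, ±0.75 K run
bias spread. The default ("true") parameter sets of
`default_pheno_params()` were chosen once so that the synthetic truth
blooms in the observed apple window (DOY ≈ 110–125), baseline seasons
essentially always complete chilling, and the end-of-century
unfulfilled fraction stays in the 0–15% class; model 5's strong
photoperiod damping ($c = 2$, forcing from January 1) keeps the
chilling-free model advancing in step with the chilling models rather
than degenerating into a pure temperature tracker.

What the generator does *not* emulate: spatial correlation between
grid points (each point's noise is independent), diverging warming
rates or transient behaviour of real RCMs (all runs share the linear
trend, so the across-run variance $M$ stays small and the synthetic
time of emergence is much earlier than for a heterogeneous real
ensemble), orography, weather regimes, or the real observation network.
Passing tests on this generator therefore demonstrate the
*correctness of the chain's algebra and algorithms* and the
qualitative directions (delayed dormancy release, advancing bloom,
faster-advancing spring freezes, non-increasing frost risk), not
quantitative agreement with any real region.

## Numerical choices and degenerate inputs

* Chilling state floored at zero for Utah (vectorised as
  $S_t - \min(0, \min_{\tau\le t} S_\tau)$, exact).
* Quantile-map knots are forced non-decreasing (`cummax`) before
  inversion; numerically flat stretches are dropped.
* Constant (zero-variance) distributions get an identity-plus-shift
  transfer function.
* Kriging targets coinciding with a sample short-circuit to the sample
  value; duplicate sample locations raise an informative error.
* A zero signal makes $F$ infinite at that year, never `NaN`.
* `delta_30yr()` demands at least 75% of a window's years to carry a
  value — warm late-century windows can lose a quarter of their
  seasons to unfulfilled chilling.
* Leap years: seasons are 365 or 366 days; all DOY arithmetic uses the
  actual calendar of the season.

## Problem sizes

The shipped tests and the acceptance script run the chain at desk
scale, chosen to exercise every code path with comfortable statistics:
ensembles of 2–5 runs on 1–4 grid points over 150 years, calibrations
on ~30 seasons with two annealing chains, $10^4$ null simulations for
the test-size checks, and 100 random fixtures per brute-force oracle.

## Known limitations

Frost severity, duration and damage economics are out of scope, as are
radiation-frost physics, variety genetics and map rendering. The
spline anchor scheme and the parallel-model gating are canonical
stand-ins where the literature admits several variants; both are
isolated behind small functions (`daily_to_hourly()`, `season_core()`)
if a user needs a different convention.
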