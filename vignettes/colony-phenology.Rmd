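---
title: "Methods: occupancy phenology and windchill density models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy phenology and windchill density models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyphen)
```

## The problem

Emperor penguin colonies are censused mostly from satellite imagery taken
late in the breeding season (September to December), when there is enough
light. Two confounders stand between a measured colony area and the number
that matters ecologically — breeding pairs and fledged chicks:

1. **Density fluctuates with weather.** Birds huddle when it is cold, so
   the same number of animals can occupy an order of magnitude more or less
   ground from one hour to the next.
2. **Occupancy fluctuates with phenology.** Late in the season only a
   weather- and date-dependent fraction of the adults is ashore, chicks mix
   with adults, and failed breeders have left.

`colonyphen` addresses both with a pair of mechanistic models plus Bayesian
inference: a *windchill model* converting meteorology to expected colony
density, and a *phenological occupancy model* describing who is present at
the colony on each day of the season.

## Windchill model

Meteorological drivers combine linearly into an apparent temperature

$$T_a = T + c_W W + c_R R + c_H H,$$

with air temperature $T$ (°C), wind speed $W$ (m/s), solar radiation $R$
(W/m²) and relative humidity $H$ (percent, 0–100). Expected colony density
is a falling sigmoid of $T_a$:

$$\rho(T_a) = \frac{\rho_{\max}}{1 + \exp\big((T_a - T_c)/b_0\big)},$$

saturating at the hexagonal packing limit for 0.3 m circles,
$\rho_{\max} = (\pi / 2\sqrt{3}) / (\pi \cdot 0.15^2) \approx 12.8$
animals/m². $T_c$ is the apparent temperature at which density is half of
$\rho_{\max}$; $b_0$ sets how sharply the birds respond.

Calibration ([`fit_windchill()`]) treats density observations (interpolated
counts divided by measured area) as lognormally distributed around
$\rho(T_a)$ — errors in count data are multiplicative, which is also why all
error reporting in this package is *geometric*
(`geometric_error()`: a 1.25-fold over- or underestimate is 25%). Priors are
uniform on wide physical ranges with the signs physics dictates (wind cools:
$c_W \in [-5, 0]$; sun warms: $c_R \in [0, 0.1]$; humidity either way:
$c_H \in [-0.5, 0.5]$; $T_c \in [-60, 10]$; $b_0 \in (0, 20]$), and the
walker ensemble starts from the log-linear regression of density on the four
variables, which estimates the sigmoid's tail slopes. The observation sd
`sigma_log` is a sixth parameter with a half-normal(0.5) prior.

## Phenological occupancy model

A season runs March 1 to February 28. Internally every event time lives on
a continuous day-of-year axis of a non-leap reference calendar (March 1 =
day 60, the following February 28 = day 424), so day-of-season = day − 60;
the arrival parameter `t0` is day-of-year, matching its physiological
bounds (day 50 ≈ Feb 20 to day 150 ≈ May 30).

Fourteen parameters describe one colony-season (`phenology_params()`):
arrival peak `t0` and spread `dt0`; courtship duration `m`; female absence
`b` with spread `db`; breeding pairs `BP`; non-breeder ratio `NB`; hatching
and fledging success `Hr`, `F`; and the foraging-trip ramp `c_max`, `c_min`
(days ashore per trip), `s_max`, `s_min` (days at sea), `s_fem` (the
females' shorter first post-hatch trip).

The model expands these into a fixed, ordered set of *Gaussian phenological
events* per cohort (female breeders, male breeders, non-breeders, chicks):
each event has a mean day, a spread, and a signed magnitude (positive =
arrival wave, negative = departure wave). The expected number present is
the signed sum of event CDFs,

$$N_c(t) = \sum_{e \in c} M_e \, \Phi\!\left(\frac{t - \mu_e}{\sigma_e}\right),$$

clipped at zero against floating-point undershoot. The event structure is:

* arrival of `BP` females, `BP` males and `NB·BP` non-breeders at `t0`
  (sd `dt0`);
* departure of females and non-breeders after courtship at `t0 + m`
  (sd `dt0` — courtship is equally long for all breeders, so the arrival
  and first-departure spreads coincide);
* female return at hatching, `t_H = t0 + m + b`, with magnitude `Hr·BP`
  (failed breeders do not return as feeders); all males depart one day
  later (the parental switching overlap, fixed at 1 day; the field reports
  only "a short overlap");
* two guarding-phase trips per sex at (`s_max` at sea, `c_max` ashore),
  except the females' first trip which lasts `s_fem ≤ s_max`;
* chick "entry" at thermal emancipation — the moment chicks become
  countable — placed at the end of the guarding trips, midway between the
  two parents' emancipation departures;
* seven crèching-phase trips per sex whose at-sea and ashore durations
  shrink linearly from (`s_max`, `c_max`) to (`s_min`, `c_min`), in line
  with the observed decline of trip durations through chick rearing. Trip
  counts (2 guarding, 7 crèching) are structural, not free parameters:
  freeing them destabilises the fit into many local optima;
* pair attrition from `Hr` down to `F` allocated linearly across the seven
  crèche trips (the simplest monotone allocation; the allocation shape is
  not observable from count data), with the abandoned chick leaving around
  the failed trip's would-be return;
* fledging, which empties surviving chicks and both parents.

Every event after the female return shares the spread `db ≥ dt0`.
Bookkeeping is exact: `fledged + dead_chicks + lost_eggs = BP` for every
valid parameter set (`breeding_outcome()`), and per-cohort signed
magnitudes sum to zero — everyone eventually leaves.

An individual-based simulation (`agent_oracle()`) provides an independent
route to the same expectation: each bird draws one timing offset for its
arrival/courtship block and one for everything after the female return, and
each pair draws Bernoulli hatching and per-trip failure fates. Expected
counts match the analytic curve exactly, so any systematic discrepancy
beyond binomial noise exposes a bookkeeping bug; the test suite compares
the two on random parameter sets at 100,000 pairs.

## Inference

Counts are fitted with independent lognormal errors and a single
season-level `sigma_log` (half-normal(0.5) prior); a floor of half an
animal guards `log(0)` on empty-colony days. Priors on the 14 parameters
are uniform on the physiological boxes with the ordering constraints
(`c_min ≤ c_max ≤ s_min ≤ s_max`, `c_max ≤ s_fem ≤ s_max`, `F ≤ Hr`,
`db ≥ dt0`). Multiple counts within a civil day are averaged before
fitting.

Sampling uses an in-package affine-invariant ensemble sampler (stretch
move): it needs no proposal tuning and is invariant to the strong linear
correlations these posteriors show. The default configuration retains
13,200 posterior samples. Full fits start from a data-driven guess (the
courtship plateau is about `(2 + NB)·BP`; the incubation level is `BP`)
refined by Nelder–Mead before the walkers are scattered in a small ball
around it. Diagnostics (acceptance fraction, autocorrelation-based
effective sample size) ship with every fit; an acceptance rate below 5%
triggers a warning rather than an error.

Two modes:

* **Full mode** (`fit_phenology()`): all 14 parameters plus `sigma_log`
  from a season of ground counts, normally adults-only — the chick curve is
  then a genuine prediction.
* **Satellite mode** (`fit_satellite()`): with a handful of late-season
  total counts the full model is unidentifiable, so only `BP` and `F` are
  free; everything else is fixed to supplied defaults and the arrival date
  is anchored astronomically (below).

## Astronomical anchoring

Hatching timing tracks the end of the polar night: the female return is
placed 27.4 days (configurable) after the first sunrise after midwinter, so
`t0 = sunrise + 27.4 − m − b`. `first_sunrise_after_midwinter()` scans civil
days from the June solstice and returns the first on which the sun's
maximum altitude (at local solar noon, declination by the standard
low-precision Fourier series) exceeds a horizon threshold.

The threshold convention matters at these latitudes. The common
refraction-plus-semidiameter definition (−0.833°) would abolish the polar
night entirely at 66°40'S — the sun would graze the horizon on the solstice
itself — contradicting the expected late-June first sunrise there. A
geometric-horizon criterion (solar centre altitude > 0°) reproduces the
expected dates at both reference latitudes to within a day (day-of-year 180
at 66°40'S, 209 at 70°40'S, as the acceptance checks verify), so 0° is the
default, exposed as the `horizon` argument.

## Synthetic seasons

`generator_spec()` bundles ground-truth phenology and windchill parameters
with a weather process and noise levels; `simulate_season()` emits the
three observation streams a campaign would yield. Defaults are chosen once
to represent a realistic mid-size colony: the "pointe-geologie" preset
(3900 pairs, arrival peak day 97, `Hr` 0.85, `F` 0.70, trips shrinking
18→8 days at sea and 3→1.5 days ashore) and an "atka-bay" preset (8600
pairs, arrival ~3 weeks later). These are constructed, not field-fitted,
values — they also serve as the satellite-mode fixed defaults and are
labelled synthetic wherever they appear.

The weather process is deliberately simple: seasonal plus diurnal
sinusoids with Gaussian noise for temperature, truncated Gaussian wind,
clipped Gaussian humidity, and solar radiation driven by the site's actual
solar altitude with lognormal cloudiness. Counts add median-unbiased
lognormal noise to the occupancy curve (or come from the agent simulation
when integer counts are wanted); areas invert the windchill model,
`A = N/\rho(T_a)`, skipping times when the predicted density falls below
10⁻³ animals/m² (an essentially empty colony has no meaningful area).

What the generator does *not* emulate: weather autocorrelation beyond the
sinusoids, observation gaps and censoring, inter-annual parameter drift,
density dependence of windchill parameters on body condition, or
non-Gaussian event shapes. Passing recovery tests therefore demonstrate
correctness of the machinery under the models' own assumptions, not
robustness to real-data misspecification.

## Numerical choices

* Gaussian CDFs are evaluated exactly (no truncation); occupancy is clipped
  at zero only against floating-point undershoot.
* Count floor 0.5 animals on both sides of the lognormal likelihood.
* Density floor 10⁻⁴ animals/m² inside the windchill likelihood.
* Weather-to-image matching: nearest record within ±30 minutes, else the
  image is skipped with a warning naming it.
* The conversion factor `CF = BP / mean(A)` uses all supplied areas unless
  a day-window is given; outlier seasons are never excluded silently.
* Seeds are mandatory for every stochastic entry point; fits are bitwise
  reproducible from (data, config, seed).

## Identifiability limits

Adults-only counts constrain the *product* of pair survival and the
colony-attendance fraction during chick rearing, not the factors
separately: lowering fledging success `F` while lengthening colony stays
(`c_max`, `c_min` up, `s_min` down) leaves the expected adult curve nearly
unchanged. The profile log-posterior is flat over a wide range of `F`, so
its posterior mean can sit well away from the truth even for
well-specified synthetic data, while `BP` (pinned by the incubation
plateau, when only the `BP` males are ashore) and the event *dates* are
recovered sharply. `Hr` is intermediate: the likelihood profile peaks near
the truth, but the posterior mass skews low because the ridge is cut off
at `Hr ≤ 1`. Chick-count predictions inherit this uncertainty. Users who
need tight breeding-success estimates should either fit total counts that
include chicks, or fix the trip-duration ramp from telemetry. The
satellite mode sidesteps the ridge entirely by fixing the attendance
parameters, which is why two free parameters suffice for sparse data.

The noiseless limit is also worth noting: with exact data the posterior
collapses into a `sigma_log → 0` funnel that small ensembles traverse
poorly; the test suite uses a wider, longer ensemble there.

## Problem sizes used by the tests

The suite exercises: oracle equivalence at 100,000 pairs on five parameter
sets; conservation on 1000 random parameter sets; full-mode recovery on one
synthetic season of 52 weekly adult counts at 10% noise (64 walkers, 2500
burn-in steps, 13,248 retained samples); satellite-mode recovery from 6
points at 10% noise; windchill recovery from 200 paired observations at
20% density noise. These sizes are the package's reference experiment
scale; larger runs only tighten the Monte-Carlo slack.
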