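---
title: "vegfire: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vegfire: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vegfire` simulates, on a small grid and at annual-to-daily resolution,
the interaction of three model switches that dominate structural
uncertainty in vegetation–fire–carbon projections: the fire-occurrence
algorithm (unlimited ignitions, suppression, or stochastic ignition), the
CO₂ fertilization effect (on or off), and a warming, summer-drying
climate. This vignette documents the model equations and assumptions, the
parameters that matter and their defaults, the synthetic-data generator,
the numerical choices, and the limits of what desk-scale runs can show.

## 1. Synthetic climate generator

The generator replaces gridded observational and downscaled-GCM forcing
with a seeded statistical emulator. Each cell-month receives:

* a **monthly climatology** of noon maximum temperature, diurnal range,
  precipitation, relative humidity, wind, and wet-day probability,
  representing a maritime regime with mild wet winters and dry summers;
* **static spatial structure**: a north–south temperature gradient
  (±1.5 °C across rows) and a west–east precipitation gradient
  (×0.70–×1.40 across columns), plus small seeded cell-level offsets —
  a stand-in for orography, so that fire danger and vegetation boundaries
  vary in space;
* **interannual noise**: Gaussian anomalies for temperature (regional,
  shared across all cells, sd 0.8 °C; plus cell-level, sd 0.3 °C) and
  mean-one lognormal factors for precipitation (regional sdlog 0.25,
  cell sdlog 0.30 — a monthly CV of roughly 0.4). Relative humidity is
  anticorrelated with the temperature anomaly (−3 % per °C). The shared
  regional component makes drought years regionally coherent, which is
  what lets large fire years synchronize across cells;
* **trends**, expressed directly as the period contrasts they must
  produce. Temperature follows a flat 20th century and a linear ramp from
  2011 such that the 2071–2100 mean annual maximum temperature ends
  4.4 °C above the 1971–2000 mean, and the Apr–Sep mean temperature
  4.8 °C above (minimum temperatures warm faster than maxima to make up
  the difference). Seasonal precipitation factors are piecewise linear
  with anchors at 1895/1924/1971/2000/2036/2100, solved so that annual
  precipitation rises 4 % across the 20th century and a further 6 % by
  the late 21st, while Apr–Sep precipitation rises 6 % over the 20th
  century and then falls 15 % from the late 20th to the mid/late 21st.
  `climate_trend_summary()` recomputes these contrasts from any generated
  forcing; with the default noise the temperature contrasts recover to
  within ±0.2 °C and the precipitation ratios to within ±5 %.

The CO₂ trajectory is a piecewise-linear interpolation of a small embedded
table (historical concentrations joined to a high-emissions pathway
reaching ~936 ppm in 2100, crossing 350 ppm in the late 1980s); the
constant mode holds every year at a preindustrial 280 ppm — the
conventional round value, used because "preindustrial" is not otherwise
pinned down. Soils are lognormal in depth with plant-available
water-holding capacity `depth × texture_fraction` (default 1200 mm ×
0.15 = 180 mm), and the non-human-affected (NHA) mask defaults to 1
everywhere.

**What the generator does not emulate:** spatial autocorrelation beyond
the fixed gradients (no weather fronts), ENSO-like interannual
persistence, realistic topographic rain shadows, humidity–precipitation
coupling at daily scale, and observed extreme-value tails. Passing tests
therefore demonstrate internal consistency and mechanism, not forecast
skill on real landscapes.

## 2. Fire weather

Monthly temperature, humidity, and wind are interpolated to days with a
natural cubic-spline basis over month midpoints (a fixed 365-day
calendar; the basis is precomputed once, so daily fields are a single
matrix product). Daily precipitation is generated by
`disaggregate_precip()`: wet days are Bernoulli draws at the month's
wet-day probability, wet-day amounts are exponential, and the vector is
rescaled to sum exactly to the monthly total — conservation holds by
construction, and the disaggregation distribution is a declared default
rather than an inference from any particular model's internals.

The standard daily equations of the Canadian Fire Weather Index moisture
codes (FFMC, DMC, DC; BUI from DMC and DC) are implemented in vectorised
form, with day-length factors for mid northern latitudes. Two numerical
notes, both verified by the test suite's independent scalar transcription
of the same published equations:

* the FF-scale conversion `m = 147.2(101 − F)/(59.5 + F)` is not the
  exact algebraic inverse of `F(m)`, so under constant drying weather the
  iteration's fixed point sits about one FFMC point away from the naive
  image of the drying equilibrium — this is a property of the standard
  code, not an implementation error;
* "drying monotonicity" (hotter or drier air never lowers FFMC at fixed
  rain) holds in the drying regime only. In the wetting regime a hotter
  day lowers the wetting equilibrium but also speeds the approach to it,
  and FFMC can legitimately end lower. The property tests are scoped
  accordingly.

Codes are computed within a configurable fire season (April–October by
default), starting each season from the conventional start-up values
(FFMC 85, DMC 6, DC 15). This plays the role of an overwinter reset:
fires cannot occur outside the season window, so winter code values are
never consulted. The indices depend only on weather — never on carbon
pools — which is what makes fire occurrence identical across scenarios
that share weather.

## 3. Fire occurrence

Per cell-day, with all threshold comparisons strict (ties do not ignite):

* **FF:** fire iff FFMC > FFMC threshold and BUI > BUI threshold.
* **FS:** the same with both thresholds multiplied by
  `suppression_factor`.
* **SF:** three stages evaluated in order — ignition-source exposure
  (Bernoulli, `p_ignition_source` = 0.001 per cell-day), the fuel gate
  (both codes above `threshold_fraction` = 0.6 of their thresholds), and
  fire initiation (Bernoulli with the Chapman–Richards probability
  `s = (1 − exp(−k · max(x − 0.6, 0)))²` of the FFMC threshold fraction
  `x`, with `k = −ln(0.01)/(0.99 − 0.6) ≈ 11.81` so that `s(0.99) =
  0.9801`). The printed form of the curve's offset argument is
  implemented as the *current* FFMC fraction minus the minimum fraction,
  clamped at zero — the only reading under which the curve is zero below
  the minimum and near one at the maximum. BUI participates in the gate
  stage only. The maximum-fraction default follows the stated value 0.99;
  the alternative 1.0 that appears in illustrative material is available
  via configuration.

Fire is a discrete annual event: at most one fire per cell-year, at the
first qualifying day. The FFMC threshold for conifer forest is 86; the
**BUI threshold is a calibrated default (200)** — no per-type BUI value
is published, so it was chosen, once, so that the default synthetic
climate yields an unlimited-ignition fire regime in the single-digit to
low-double-digit AWF range historically, rising steeply in the 21st
century, with stochastic-ignition AWF below it in every period. By
default all four vegetation categories share the same FFMC/BUI
thresholds (per-type values are configurable); this makes occurrence
independent of the vegetation map and hence identical across scenarios
sharing weather. Fire return intervals do differ by category (conifer
150 yr, temperate mixed 100, subtropical mixed 50, other 30) and shape
burned fractions, not occurrence.

The **suppression factor defaults to 1.03**, not a larger value, for a
structural reason: FFMC's scale is strongly compressed near its top
(drying equilibria rarely exceed ~93), so a factor of 1.1 would put the
suppressed FFMC threshold (94.6) out of reach and extinguish essentially
every fire. At 1.03 (FFMC 88.6, BUI 206) suppression removes the marginal
fires and leaves the severe ones — the intended behavior of a
threshold-raising suppression rule.

**Randomness design:** stage-1 and stage-3 uniforms come from dedicated
substreams derived from the master seed (as do climate,
precipitation-disaggregation, soil, and mask draws), with a fixed
consumption order per day. Toggling the fire mode or the CO₂ mode
therefore perturbs no other component's draws, and all scenarios of a
factorial see identical ignition exposure — common random numbers, which
is what makes cross-scenario differences attributable to the switches
alone.

## 4. Fire effects

The burnable fraction is `min(1, tsf/FRI)` — linear in time since fire
(`tsf`), a deliberate simplest-form choice since only the dependency, not
its shape, is prescribed. `tsf` resets to zero in a burn year and starts
at 10 years (so early-century first fires burn modest fractions rather
than whole cells). Severity — the mean of the FFMC and BUI threshold
fractions at the fire day, capped at 1 — scales the consumption
fractions linearly. Defaults per pool (at full burn, severity 1): leaf
0.9 and litter 0.7 consumed, standing dead 0.5 consumed, 15 % of live
wood killed of which 10 % is consumed and the rest transferred to
standing dead; soil carbon and live roots untouched. These are declared
surrogates for fuel-model detail that lives outside this package; all are
configurable. Carbon is conserved identically: consumed carbon leaves the
system as the fire flux, killed carbon moves live → dead.

## 5. Carbon surrogate

The full biogeochemistry of a production DGVM is replaced by a surrogate
that preserves the reported quantities and their identities:

* **NPP** = `npp_max × f(T) × f(W) × multiplier`, with `npp_max` =
  1300 g C m⁻² yr⁻¹, a triangular temperature response in Apr–Sep mean
  temperature (0 at 0 °C, optimum 18 °C, 0 at 38 °C), and a water scalar
  equal to the annual ratio of actual to potential transpiration from a
  monthly soil-water bucket. `npp_max` was calibrated once so that the
  default historical simulation produces NPP near 1150–1200 g C m⁻² yr⁻¹
  and ecosystem carbon near 52 kg C m⁻², the magnitudes typical of
  productive temperate conifer forest.
* **CO₂ multiplier** `1 + (effect_param − 1) log₂(C/350)` applied to
  production, and transpiration demand *divided* by it. The direction of
  the transpiration adjustment is ambiguous in the source formulation;
  division (water-use efficiency rises with CO₂) is the declared choice,
  so high CO₂ both boosts production directly and relieves water stress.
  Disabling the effect is done by holding the CO₂ trajectory at its
  preindustrial constant (the run-protocol convention); setting
  `effect_param = 1` is also supported and gives a multiplier of exactly 1.
* **PET** is a Hamon-type temperature/daylength formulation, zero at or
  below freezing (a frozen-month convention; Hamon's formula itself is
  positive at 0 °C).
* **Pools**: leaf/wood/root (live) and standing dead/litter/soil (dead),
  with fixed allocation (0.3/0.5/0.2), first-order live turnover (0.25,
  0.03, 0.12 yr⁻¹), and dead-pool decomposition (0.08, 0.12, 0.012 yr⁻¹)
  modified by a Q10 = 2 temperature response (reference 10 °C) and a
  linear moisture response. Humification fractions route 50 % of standing
  dead decay to litter and 30 % of litter decay to soil; the remainder is
  heterotrophic respiration. The identities NEP = NPP − Rh,
  NBP = NEP − consumed, and Δ(ecosystem C) = NBP hold exactly by
  construction (to floating-point rounding; the ledger tests assert
  1 part in 10⁶).

Runs start from the analytic steady state of the pool system under
first-year climate, followed by a 50-year fire-free spin-up cycling the
first 30 years of climate; the spin-up is excluded from all outputs. The
spin-up length and scheme are declared defaults (no spin-up protocol is
prescribed by the problem), and the small early-century NBP transients
that remain are visible in the first reported period.

## 6. Vegetation typing

A cell's category — conifer, temperate mixed, subtropical mixed, other —
is decided each year by a carbon-gated warmth index: cells with live
woody carbon below 500 g C m⁻² or growing season under 500 degree-days
are "other"; among forests, the Apr–Sep mean temperature, exponentially
smoothed with a 15-year e-folding time (vegetation inertia; there is no
succession model, so smoothing is the only lag), selects conifer below
20.20 °C, temperate mixed to 21.20 °C, subtropical mixed above. The two
warmth boundaries are **calibrated defaults**: actual biome-threshold
tables are external to this package, so the boundaries were set, once,
against the default synthetic climate so that the historical period is
conifer-dominated (≥85 %) and the late-21st-century warming splits the
grid roughly a third each into conifer / temperate mixed / subtropical
mixed. Period maps use the modal category per cell over each 30-year
period, ties broken to the first-listed category; distributions are
area-weighted.

Because occurrence thresholds are category-independent by default and the
carbon gate is far below simulated wood stocks, vegetation trajectories
are driven by climate alone and are essentially identical across
scenarios — the cross-scenario comparison in the acceptance tests bounds
the differing cells at under 5 %.

## 7. Metrics and reporting

AWF is the percentage of study area in cells with any fire in a year; FAB
the area-weighted mean burned fraction among burning cells; TAB the
percentage of total area burned. Computing TAB as Σ(area × fraction)
makes the fractional identity TAB = AWF × FAB hold to rounding (asserted
at 10⁻⁹); TAB ≤ AWF always. FAB is undefined in zero-fire years — it is
reported as 0 with a `fab_defined` flag and **excluded from period
means**, since the metric only exists over cells with fire. Period
summaries report mean and standard deviation **across years** (across
cells is the other possible reading; across years is what the annual
series support). Triangle smoothing uses weights `hw + 1 − |lag|` over
±`hw` years (default 8), renormalized at the series edges, so constants
are preserved and `hw = 0` is the identity. Carbon summaries report AGB
(live wood), AGD (standing dead plus a 0.3 woody share of litter), AGT =
AGB + AGD, and the live:dead ratio with an undefined-flag (never an
infinity) when dead carbon is zero. `mask_weight()` multiplies any
density field by a per-cell area fraction in [0, 1], e.g. an NHA mask.

## 8. Problem sizes and runtime

The default configuration — a 20 × 20 grid of 16 km² cells, monthly
climate 1895–2100 with a 214-day fire season stepped daily, six
scenarios — runs the full factorial in well under a minute on one core;
the fire-weather engine runs once and is shared by all scenarios. The
test suite uses smaller grids and windows for module tests and one
default-size factorial for the scenario-contrast checks. These sizes were
chosen to make the full factorial cheap enough to iterate on
interactively; all of them scale via the configuration.

## 9. Known limitations

* No fire spread between cells, no ignition-location structure (human
  infrastructure, lightning climatology), and no multi-run ensemble
  statistics — occurrence is cell-local and single-draw.
* The carbon surrogate has no nitrogen cycle, no species or age
  structure, and no disturbances other than fire; its rate constants are
  calibrated for plausibility, not fitted to observations.
* Vegetation typing has no dispersal, succession, or establishment
  limits; types track smoothed climate instantly beyond the 15-year
  inertia.
* The synthetic climate's realism limits are listed in §1; in particular
  regional noise is the only spatial correlation structure.
* FAB under unlimited ignitions is sensitive to the time-since-fire
  initialization for the first decades of a run.
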