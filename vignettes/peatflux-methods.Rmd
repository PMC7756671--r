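---
title: "Methods: chamber flux estimation, upscaling and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber flux estimation, upscaling and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatflux)
```

# The measurement model

A static closed chamber traps a headspace of height $h$ (the
volume-to-area ratio, m) over the soil. A constant soil flux $F$
(g element ha⁻¹ day⁻¹) changes the headspace mixing ratio linearly at rate

$$ s = F \,/\, \left(10^{-9}\, \tfrac{P}{RT}\, h\, M \times 1440 \times 10^4\right) \quad \text{[ppb min}^{-1}\text{]}, $$

where $P/(RT)$ is the molar density of air (ideal gas; $P$ in Pa, $T$ in
K) and $M$ the grams of reported element per mole of gas (28.014 g N for
N₂O, 12.011 g C for CH₄). `fit_flux()` estimates $s$ by ordinary least
squares on the four timed samples and `convert_slope()` inverts the
relation above. The linear model assumes the deployment is short enough
that the concentration gradient does not feed back on the flux; we fit no
nonlinear (HMR-type) chamber models because the sampling scheme the
package targets uses linear fits throughout.

**Quality control.** Field series fail in two characteristic ways: one
vial leaks (a point drops back toward ambient) or accumulation saturates
late in the deployment. Both leave a four-point fit with low R² that a
single-point deletion repairs. The default `qc_policy()` triggers the
three-point fallback when the four-point R² < 0.90 *and* the best
leave-one-out R² ≥ 0.95, choosing the deletion with maximal R². The
source monitoring program reports only that ~7% of its fluxes used
three-point fits, not its criterion; both thresholds are exposed, and the
joint condition avoids discarding a point from series that are merely
noisy (no deletion rescues those). A flat series has R² defined as 0 with
slope 0 (avoiding 0/0), and fewer than three usable points yields a
`rejected` estimate with missing flux. When deployment temperature or
pressure are unrecorded, defaults of 27 °C (regional mean air temperature)
and 101.325 kPa are imputed. Chamber *air* temperature enters the
conversion; soil temperature is carried only as a covariate.

# Minimum detectable flux

`detection_limit()` simulates the zero-flux null: four-point series at the
ambient concentration perturbed by the gas chromatograph's analytical
noise (multiplicative, coefficient of variation `cv`, or an absolute SD in
ppb), fitted and converted exactly like field data. Two policies turn the
null into a limit:

* `"two_sided_95"` — the 95th percentile of |flux|, ≈ 1.96 × null SD;
* `"calibrated"` (default) — `factor` × null SD with `factor = 1.25`.

The calibrated factor is documented rather than derived: the tabulated
multiplier of the Parkin-style method is not published for this
deployment scheme, but the published N₂O limit (6.8 g N ha⁻¹ day⁻¹)
divided by the analytic null SD at the program's GC precision
(330 ppb × 9% / √Σ(t−t̄)² propagated to areal units = 5.44 g N ha⁻¹ day⁻¹)
gives 1.2503, fixed once as 1.25. The analytic SD, the MC SD and the
limit's linear scaling in `cv × ambient` are all property-tested. Fluxes
inside the band are flagged by `flag_below_detection()` (boundary
inclusive) and always retained — censoring small fluxes biases budgets.

# Aggregation and uncertainty

Replicate chambers (nine per stratum by default) give monthly stratum
means with SE = SD/√n; missing replicates reduce n. `annual_cumulative()`
integrates the piecewise-linear interpolant of the monthly daily-rate
series over an April–March budget year (365/366 days), extrapolating as a
constant from the first/last measurement to the window edges — the
minimal assumption, and standard chamber-budget practice. The integral is
linear in the measured values, so each date carries an explicit trapezoid
weight (days); the SE propagates per-date SEs through those weights
assuming independence between months. `site_scale()` combines strata with
mapped area fractions ($\sum w_i x_i$, SE $= \sqrt{\sum w_i^2 SE_i^2}$);
the default SE therefore propagates monthly replicate spread through
interpolation and weighting, with no between-stratum or between-month
covariances (none are estimable from the design). Published inventory
fractions can sum to 1.01 as printed; validation tolerates |Σw − 1| ≤
0.015 and uses the weights as given, because renormalizing would not
reproduce the published site-scale values. Interpolating per stratum and
then weighting, versus weighting monthly and then interpolating, agree
exactly when all strata share measurement dates (both are linear in the
same values); the per-stratum order is used. Multi-year summaries are the
mean of yearly budgets with SE = SD/√N. Significance between sites or
years follows the non-overlap of mean ± SE intervals (closed intervals:
touching endpoints are *not* different). Report tables round half-up at
one decimal, matching the printed convention.

# Hotspot rule

`detect_hotspots()` flags a chamber whose history contains at least three
values strictly above $Q_3 + 3\,(Q_3 - Q_1)$. The criterion's "upper edge
of the 50% percentile" is read as the upper quartile — the top of the
boxplot's central box — which is the standard reading of the cited
boxplot rule. Quartiles use linear interpolation between order statistics
(R type 7); the estimator is configurable because the originating
software's default is unknown. The rule is applied per chamber and per
gas. Fewer than four values leave quartiles meaningless: the record is
skipped with a warning. There is no low-tail rule; strong sinks are not
"coldspots" by this criterion.

# Driver models

`fit_driver_model()` fits the catalogued functional forms by OLS
(`stats::lm` underneath): multiple linear on the raw flux or on
ln(flux + 4); a quadratic in one covariate; an exponential fitted
log-linearly and back-transformed with `exp`; and a logarithmic form in
`log(x + shift)`. The +4 offset (g N ha⁻¹ day⁻¹) makes the largest
observed N₂O uptake representable and is exposed as `LN_FLUX_OFFSET`;
responses at or below −offset abort with the offending rows listed.
`bin_and_fit()` reproduces class-binned fitting (e.g. 10% WFPS, 10 cm
water-table, 1 °C classes): bin means first, then an unweighted fit to
the means — the published figures annotate bin counts but state no
fitting weights, so weighting by n is optional. P-values are two-sided
t-tests on OLS SEs with no multiplicity correction (models are reported
individually). Model selection is the user's: the bundled
`driver_catalog()` lists the published equations (response spec, form,
terms, coefficients, R², n) as fixtures and generative truths, not as an
automated search space. Two figure-only bivariate/exponential fits whose
coefficients are not printed in text are supported generically but have
no numeric regression test.

# Soil covariates

`wfps()` implements $100\,(m_G/100)\,BD / (1 - BD/PD)$ with particle
density 1.4 g cm⁻³ (tropical peat). Gravimetric moisture is % of dry
mass and exceeds 100% routinely in peat; WFPS > 100% marks
supersaturation (water table above the surface) and is flagged, never
truncated. Stratum-level WFPS should use stratum-mean bulk density; BD ≥
PD is an error (non-positive porosity). `net_rates()` divides the change
in total inorganic N (net mineralization) and in NO₃⁻ (net
nitrification) by the incubation duration (default 10 days); negative
mineralization is immobilization.

# The synthetic campaign

`campaign_config()` states the world the generator emulates: 3 sites ×
up to 4 palm-status/microtopography strata (area fractions from the
published inventory, with the heavily degraded site's printed fractions
normalized from their sum of 1.01), 9 replicate chambers, 40 monthly
campaigns from April 2015, samples at 0/10/20/30 min in a 0.25 × 0.30 m
chamber, GC CVs of 9% (N₂O, 330 ppb ambient) and 1% (CH₄, 1522 ppb), and
a 7% anomaly rate split between leaked points and saturating
nonlinearity (one anomaly per series at most).

Drivers are sinusoids on the calendar month plus AR(1) chamber noise —
the simplest structure reproducing the observed wet/dry contrast: rain
peaking January–April (> 400 mm at full amplitude) with a June–September
trough (< 200 mm); water table around −8 cm in hollows with ±20 cm
seasonal swing (flooding possible), hummocks sitting
`wt_hummock_offset_cm` lower (default 12 cm, between the observed 7 cm
gap at degraded sites and 16 cm at the intact site); WFPS tracking the
water table around the observed 58–93% range; air/soil temperatures near
30/25.5 °C with ±1.5 °C seasonality; higher soil respiration on hummocks
and under low water table; NO₃⁻ lognormal below ~4 mg N kg⁻¹; net
nitrification around 0.3 mg N kg⁻¹ day⁻¹. `seasonal_amplitude` and
`driver_noise_sd` scale the deterministic and stochastic parts (both 0
gives identical months, the degenerate check). Within-month replicate
variance is not published; it is a configuration choice, with the flux
noise SD defaulting to 200 g C ha⁻¹ day⁻¹ on the default CH₄ truth —
wide enough for realistic replicate spread, narrow enough that chamber
depletion stays physical.

True fluxes evaluate a named form (`linear`, `log_offset_linear` with
back-transform exp(η) − 4 so uptake occurs, `exponential_wt`,
`quadratic_wfps`) with Gaussian noise on the form's response scale;
defaults take the published water-table CH₄ equation (slope 14.95,
intercept 616.09) as truth. Chamber series invert the unit conversion,
add multiplicative GC noise, and floor concentrations at 0.001 ppb — a
chamber cannot be depleted below zero, so extreme uptake saturates
(physically faithful, and the one place the synthesis/estimation round
trip is deliberately not the identity). Anomalies replace one point with
ambient (leak) or bend the series onto
$c_0 + s\tau(1 - e^{-t/\tau})$, $\tau = 20$ min (nonlinearity).

What a green end-to-end test establishes: with Gaussian noise, the
stated design, and the same monthly grid for estimate and truth, the
area-weighted annual budget is unbiased up to anomaly attenuation and its
propagated SE is conservative. What it does not establish: robustness to
non-Gaussian flux distributions, serially correlated replicate errors,
drifting GC calibration, or real hydrology — the generator makes no
attempt at flooding dynamics, plant-mediated transport or microbial
process models. Between-site biological contrasts of the source study are
not reproducible from synthetic data and are checked only as
interval-overlap arithmetic on the published values.

# Numerical choices

* Quartiles: type 7; configurable (`qtype`).
* Rounding for report tables: half away from zero at 1 decimal
  (`round_half_up()`); base `round()` is half-even.
* Trapezoid weights are computed analytically from the interpolation hat
  functions and are tested against basis-vector numerical integration.
* R² of a zero-variance response is 0 by convention everywhere.
* Rank-deficient driver fits error, naming the collinear terms.
* All simulation entry points take explicit seeds and restore the
  caller's RNG state (`(config, seed)` pairs are byte-reproducible).
* Sub-stage seeds of `simulate_campaign()` are `seed + 0..3` (drivers,
  flux noise, anomalies, GC noise).

# Known limitations

* Error propagation assumes independence throughout; shared-month
  weather makes stratum budgets positively correlated in reality, so
  site-scale SEs are somewhat optimistic on real data.
* The calibrated detection-limit factor is tied to the documented GC
  precision and deployment scheme; other schemes should recalibrate via
  `calibrate_detection_factor()`.
* The three-point QC fallback cannot distinguish a genuine outlier from
  the largest residual of an honestly noisy series when R² thresholds
  are set loosely; the defaults are deliberately conservative.
* Annual budgets from sparse or irregular sampling inherit the
  trapezoid's discretization error (tested at ~2% for a smooth seasonal
  cycle sampled monthly); no driver-based gap-filling is attempted.
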