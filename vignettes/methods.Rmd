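---
title: "Methods: from aerial sightings to seasonal distribution forecasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from aerial sightings to seasonal distribution forecasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aerialsdm)
```

`aerialsdm` models the distribution of large, surface-visible marine
animals — manta rays are the motivating case — from aerial line-transect
surveys that were usually designed for other taxa. That origin drives the
whole design: sightings are sparse and incidental, detection is imperfect
and team-dependent, effort varies with weather and platform, and the only
honest way to compare surveys is to push every one of them into a common
currency of *effective searched area*. This vignette explains the models,
the defaults, and the choices made where the design was genuinely open.

## Detection: distance sampling with two observer teams

An observer measures the angle θ from vertical to a sighted animal with a
clinometer; at flight altitude `A` the perpendicular sighting distance is
`PSD = tan(θ)·A`. The probability of detecting an animal at perpendicular
distance `x`, relative to detection on the trackline, is the key function
`g(x)` with `g(0) = 1`:

* half-normal: `g(x) = exp(-x²/(2σ²))`
* hazard-rate: `g(x) = 1 − exp(−(x/σ)^−b)`, `b > 0`

Covariates (sea state, glare, cloud, turbidity) enter on `log σ`. For
exact distances the conditional likelihood of each distance is
`g(x)/∫₀ʷ g`, truncated at `w`; distances recorded in platform-specific
bins (wing-strut marks) use the interval-censored probability
`∫_lo^hi g / ∫₀ʷ g`, with a midpoint approximation behind a flag. A
midpoint fit on binned data is exactly the fit of the midpoint data — a
tested identity.

Dual-team surveys additionally identify *duplicates*: events seen by both
the forward and aft team. Because animals carry no identifiers, duplicates
are declared by rule — equal group size, same side of the aircraft, within
15 s, angle difference under 15° — resolved greedily (smallest time
difference, then smallest angle difference, one-to-one). The
mark-recapture component stacks, for every event one team detected, a
Bernoulli trial for whether the other team detected it too, and fits a
logistic regression on distance, observer, their interaction, and any
covariates. Its intercept at distance zero gives each team's trackline
probability `p_j(0)`; under **point independence** the teams are assumed
independent only at `x = 0`, so the combined detection function is
`p(x) = [1 − (1 − p₁(0))(1 − p₂(0))]·g(x)` with `g` fit to the pooled
distances.

Average detection probability inside the strip is
`p̄ = p(0|z)·(1/w)∫₀ʷ g(x; z) dx` averaged over the empirical covariate
rows — by default the sightings themselves (whether the original analysis
averaged over sightings or effort segments is not knowable from its
description; both modes exist, sightings are the default). The CV of `p̄`
comes from a nonparametric bootstrap over sightings/events (`B` default
999; the demo config uses 40 to keep its runtime small) rather than the
delta method, so MCDS and MRDS fits are treated identically. Effective
effort for a segment is then `length × p̄ × w` (m²), the survey-specific
swept area; a `sides = 2` flag doubles it where both sides of the
aircraft are counted separately.

A caveat worth stating: the conditional-detection logistic is linear in
distance on the logit scale, while the true conditional probability under
a half-normal key is not, so `p̂(0)` extrapolates with a small positive
bias (about +0.03 at `p(0) = 0.8`, σ = 150 m, w = 300 m). This is a known
property of the standard estimator, not an implementation defect; the
recovery tests bound it rather than hide it.

## Effort on a grid and Front-Z

Analysis happens on a planar 10 × 10-km grid (a configurable projected
grid for real data; the synthetic grid is kilometre-planar so the tests
involve no projection machinery). Each trackline segment is split exactly
at the cell boundaries it crosses, so allocated length sums to segment
length to machine precision — conservation is asserted at 1e-6 relative
tolerance on 10⁴ random segments. Per cell-day, sightings and effective
effort are summed, covariates averaged weighted by allocated trackline
length (unweighted behind a flag), and the maximum bathymetric slope along
the surveyed track retained. Cells with zero effort never enter the model;
a sighting in a cell-day without effort is dropped with a warning.

Thermal fronts are summarized by **Front-Z**: the magnitude of the SST
gradient (central differences, one-sided at edges), divided by the daily
maximum over the model domain. This self-normalization keeps fronts
visible during summer warming, makes the statistic unitless in [0, 1] and
exactly invariant to adding a constant to (or rescaling) the SST field.
The daily maximum is taken over the model domain, not any wider scene —
an interpretation, flagged here, since the alternative is unknowable
without the original rasters. `0/0` (a perfectly uniform field) is defined
as 0.

## Distribution models

The response is cell-day presence/absence with a binomial logit GAM and a
`log(effort)` offset — occupancy per unit searched area, not density. Each
covariate enters as a cubic-regression-spline smooth with basis dimension
3 ("3 knots", i.e. 2 effective df), unpenalized because so small a basis
needs no penalty (penalization is available behind a flag). The tiny basis
is a deliberate guard against overprediction when extrapolating to
unsurveyed months, at the price of only dome- or S-shaped responses. The
SST × Front-Z interaction is a tensor product of the marginal bases and is
only ever tested alongside both mains (the interaction-only form is
available but not the default, the published model table being ambiguous
between the two).

Model search enumerates *all* subsets of the covariate pool, excluding
pairs with |Pearson ρ| > 0.7 (strictly; a pair at exactly 0.7 is allowed)
and never allowing chlorophyll-a and primary productivity — two proxies of
one quantity — in the same model. The lowest-AIC candidate is then pruned:
up to three tiered reductions drop the least significant smooth term
(Wald-type approximate test, α = 0.05) while any term is non-significant.
The final choice among the AIC-best model and its tiers is by tenfold
cross-validated AUC when CV is enabled; without CV it is the most-pruned
tier within 1 percentage point of the best model's deviance explained.
The rule actually applied is recorded in the returned comparison table.
CV folds are stratified by presence (the sparse class) and seeded; AUC is
the rank statistic on pooled held-out predictions, and FPR/FNR are
reported at the threshold maximizing Youden's J.

Prediction surfaces are evaluated at a fixed reference effort — the
geometric mean of training efforts, which centres the offset on the log
scale — from the shoreline to the maximum depth surveyed (1835 m for the
single-survey demo analogue, 2200 m for combined surveys); deeper cells
are masked, and cells with any covariate outside the training range are
flagged as extrapolated rather than silently trusted. Standard errors on
the probability scale use the delta method from the link-scale SE; a
parametric bootstrap over the coefficient posterior agrees within 10% in
tests.

## Ensembles, pooling, external validation

Two ways to combine surveys are provided, mirroring the two published
strategies. The **weighted ensemble** averages per-survey surfaces cell by
cell with weights `max(1 − SE, 0)`, favouring whichever survey is most
certain locally; masked components drop out and the weights renormalize.
The **combined fit** concatenates the cell-day tables — legitimate only
because every survey's effort is already in m² of swept area — and refits
the full selection procedure.

External validation uses presence-only sightings with unquantifiable
effort (opportunistic reports, other surveys). Each sighting's prediction
is divided by the same day's median prediction over valid-depth cells and
centred by subtracting one, so positive scores mean the model ranks
sighted places above typical available habitat. The summary reports the
proportion of positive scores, the mean with 95% CI, and a one-sample
t-test (one-sided, mean > 0, matching the directional claim; two-sided
available). The published description calls these "Z-score transformed"
values; only the median-ratio reading makes "subtracting one" centre the
score at zero, so that is the default, with a standardize-then-centre
mode behind a flag and the choice recorded in the output. Scores are
invariant under multiplicative rescaling of a day's surface but not under
additive shifts — also tested. Sightings with no valid prediction (masked
cell, missing day) are dropped and counted, as the same limitation arises
in practice when satellite covariates are missing.

## Centroid trends and seasonal forecasting

For each month, the probability-weighted mean latitude
`Σ lat·p·area / Σ p·area` over unmasked cells summarizes the
distribution's north-south position (areas are constant on the planar
grid and cos-latitude corrected on geographic grids). The monthly series
is fit with a seasonal ARIMA; the default order (1,1,1)(0,1,1)₁₂ applies
both the monthly and the annual difference and exposes the two
coefficients of interest, ar1 and sma1. The original orders are not
recoverable from the published description, so the default is the minimal
order consistent with it and everything is configurable. Coefficient
t-statistics use `n − d − D·period − k` degrees of freedom. Forecasts
(default horizon 60 months) report the mean with ±1 and ±2 SE bands; on a
noiseless periodic-plus-trend series the (0,1,0)(0,1,0)₁₂ recursion
continues the pattern exactly, a closed-form test of the forecasting path.

When a monthly series is *exactly* periodic, seasonal differencing leaves
zero variance and any SARIMA fit is degenerate. Real SST never repeats
exactly, and neither does the generator's: see below.

## The synthetic-data generator

The generator is first-class, tested code — it defines the study
conditions under which every property is verified. It emulates a
subtropical western-boundary shelf:

* **SST** = southern-edge mean (26 °C in the demo) − meridional gradient
  (1.2 °C/100 km) + seasonal cosine (amplitude 4 °C, July peak) + a sharp
  cross-shelf front (2 °C step at 65 km offshore) + static spatial texture
  (SD 0.3 °C) + a step-wide interannual anomaly with SD = 10% of the
  seasonal amplitude. The anomaly exists because observed seasonal cycles
  never repeat exactly; it scales with amplitude so a frozen-season run
  (amplitude 0) is exactly time-constant, and it is what keeps monthly
  centroid series away from the degenerate exactly-periodic case. With it,
  the seasonally differenced centroid series behaves like a seasonal MA
  process near the invertibility boundary — which is precisely the regime
  the real analysis reported (seasonal MA coefficients of −0.96 to −1.00).
* **Bathymetry** deepens monotonically offshore as a power law (3000 m at
  the offshore edge, exponent 1.8), slope from its cross-shelf increment;
  chlorophyll decays offshore with lognormal texture, primary productivity
  is a power of chlorophyll, a Gaussian northward jet sits at the shelf
  edge, wave height has a winter-peaking cycle.
* **Occurrence truth** is logistic with a Gaussian dome in SST (optimum
  23 °C, width 3 °C — inside the 17–32 °C band where sightings
  concentrated in the motivating study), plus linear enrichment at fronts
  and nearshore.
* **Surveys** fly east-west transects at 182 m and 185 km/h, logging
  effort segments on a fixed interval. Animals are placed by a thinned
  Poisson process with intensity `density × p(cell)` inside the simulated
  strip; each team detects independently with `p0_team·g(distance)`
  (hazard-rate σ = 130 m, shape 2.5, `p0` 0.8/0.7 in the demo — a strong
  shoulder and imperfect trackline detection, as found for the real dual
  platform). Recorded angles are exact by default, so
  `tan(θ)·altitude` reproduces placement distances to 1e-9 — measurement
  noise is opt-in (the matching-recovery property uses 2° / 2 s noise).
  Groups default to size 1, matching the duplicate rule's "equal number
  of animals" without a group-size model; a distribution can be
  configured.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: availability bias (submerged animals),
species misidentification, observer fatigue or heterogeneity beyond the
two-team structure, spatially autocorrelated residual occurrence,
projection distortion, and covariate measurement error. The detection
truth and the occurrence truth are exactly of the families being fit, so
the recovery tests verify correctness of estimation, not robustness to
misspecification (with one deliberate exception: the logistic-linear MR
component is misspecified against the half-normal truth, as it is in
practice).

## Numerical choices

* Detection likelihoods are maximized by BFGS on log-transformed
  parameters from three spread starting points; convergence tolerance
  1e-10 on the relative likelihood; variance from the numeric Hessian.
  Degenerate inputs (all-zero distances) are refused rather than fit.
* Hazard-rate strip integrals use adaptive quadrature at 1e-10 relative
  tolerance; the half-normal integral is closed-form via the normal CDF.
  The two routes agree below 1e-6 in tests.
* Truncation bounds are left-open/right-closed: a sighting exactly at
  `w` is retained, one exactly at the left bound removed. The convention
  is configurable; published descriptions rarely state it.
* Left truncation applies to the aft team only by default (its belly
  window cannot see the trackline's immediate vicinity from altitude);
  `team_rule = "all"` applies it globally. Whether the original rule was
  per-survey or global is unstated; it is a per-call argument here.
* Heading-change filtering uses the minimal circular difference between
  consecutive retained segments within a flight, so 350°→5° is a 15°
  change, and a dropped waypoint does not reset the reference heading.
* AIC ties (detection and SDM) break toward fewer parameters.
* Cell membership of a point on a cell edge belongs to the higher-index
  cell except on the grid's outer lower edges, fixed by the allocation
  midpoint rule, so allocation is exhaustive and disjoint.
* The intercept-only GAM's deviance explained is 0 by definition (not
  recomputed through floating arithmetic).

## Problem sizes

The test-suite and acceptance-script study sizes are the package's own
choices, balancing statistical resolution against a desk-scale footprint:
detection recovery uses 50–100 replicates of n = 2000 distances; MRDS
recovery n = 5000 events; GAM dome recovery 10–25 replicate surveys on a
140 × 200 km grid over 18 monthly steps (~1500 modeled cell-days each);
effort conservation 10⁴ random segments; SARIMA recovery 20–50 series of
204 months — the same length as a 2003–2019 monthly record; and the
bundled demo is a 180 × 300 km shelf, 204 monthly steps, a 36-month
dual-team survey and a 24-month single-team survey (~46,000 effort
segments in all). The demo's full run — simulation through forecasts —
takes roughly two minutes on one CPU.

## Known limitations

* Abundance and density are out of scope: the GAM predicts probability of
  presence per reference effort, not animals per km², and no
  availability-bias correction is attempted.
* Only the point-independence MRDS estimator is implemented (no full- or
  limiting-independence variants), and `p(0)` inherits the standard
  extrapolation bias discussed above.
* Smooths are deliberately tiny; genuinely multimodal responses will be
  smoothed over.
* The Front-Z gradient is central-difference only; specialized gradient
  detection algorithms (e.g. histogram-based front classifiers) are not
  reimplemented.
* No spatial autocorrelation terms; cell-days are treated as independent
  Bernoulli trials given covariates and effort.
* SARIMA order selection is manual by design; there is no auto-ARIMA.
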