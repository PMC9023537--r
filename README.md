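# aerialsdm

Species distribution modeling from dual-observer aerial line-transect
surveys, built for marine megafauna (manta rays, marine mammals, sea
turtles) sighted incidentally on shelf-scale aerial surveys. The package
carries a complete, seed-reproducible pipeline from raw sighting and effort
logs to seasonal distribution forecasts, plus a synthetic-data module that
makes every stage testable against known ground truth.

## What it does

1. **Distance sampling.** Clinometer angles become perpendicular sighting
   distances via `PSD = tan(θ) × altitude`. Detection functions are fit by
   maximum likelihood with half-normal (`g(x) = exp(-x²/2σ²)`) or
   hazard-rate (`g(x) = 1 - exp(-(x/σ)^-b)`) keys, covariates on `log σ`,
   and AIC selection. Dual-observer surveys use mark-recapture distance
   sampling (MRDS) under point independence: a conditional-detection
   logistic estimates trackline probability `p(0)`, and overall detection
   is `p(x) = p(0|z) · g(x)`. Average detection probability within the
   truncated strip is `p̄ = p(0) · (1/w)∫₀ʷ g(x)dx`, with a bootstrap CV.
2. **Effective effort.** Per-segment swept area `= length × p̄ × w`,
   transferable to distance-less surveys via shared covariates.
3. **Gridding.** Trackline segments are split exactly across 10-km cells;
   sightings and effort are summed per cell-day, covariates averaged
   (length-weighted), maximum slope retained. SST frontal gradients are
   standardized by the daily domain maximum ("Front-Z" ∈ [0, 1]).
4. **Distribution models.** Effort-offset binomial GAMs
   (`presence ~ offset(log effort) + s(covariates, k = 3)`, logit link,
   3-knot tensor smooths) are fit to every admissible covariate subset
   (pairs with |ρ| > 0.7 never co-occur; an SST × Front-Z tensor
   interaction is tested with its mains), selected by AIC with tiered
   significance pruning, compared by deviance explained and tenfold
   cross-validated AUC, and predicted as depth-masked probability surfaces
   with standard errors.
5. **Ensembles and validation.** Per-survey surfaces combine by
   (1 − SE)-weighted means; surveys pool into a combined fit in common
   swept-area units. Independent presence-only sightings are scored by
   `s = p_sighting / median(daily domain) − 1` with a one-sample t-test of
   mean > 0.
6. **Trends.** Monthly probability-weighted latitudinal centroids are fit
   with seasonal ARIMA (default (1,1,1)(0,1,1)₁₂ — monthly and annual
   differencing) and forecast with ±1/±2 SE bands.

## Worked example

```r
library(aerialsdm)

# simulate a dual-team survey over a known occurrence surface
grid <- grid_spec(cell_km = 10, nx = 12, ny = 16, lat0 = 25)
env  <- compute_front_z(generate_environment(
  grid, n_steps = 12, season_params(period = 12, peak_step = 7), seed = 1))
truth <- occurrence_model(intercept = 0.5, sst_opt = 23, sst_width = 3,
                          betas = c(front_z = 1.5, dshore_km = -0.015))
p_true <- true_probability_surface(env, truth)
survey <- simulate_survey(env, p_true, survey_scenario(
  make_tracklines(grid, steps = 1:12, spacing_km = 30),
  detection = detection_truth("hr", sigma_m = 130, shape = 2.5,
                              p0 = c(forward = 0.8, aft = 0.7)),
  density_per_km2 = 0.2, record_interval_s = 40, seed = 2))

# preprocess: truncation, condition filters, duplicate matching
sgt <- apply_truncation(survey$sightings, left_m = 3.2, right_m = 300)
eff <- filter_effort(survey$effort, sgt)
events <- match_duplicates(dplyr::filter(eff$sightings, team == "forward"),
                           dplyr::filter(eff$sightings, team == "aft"))
table(events$match)
#> aft_only         both forward_only
#>       47           67           52

# MRDS detection function, hazard-rate vs half-normal by AIC
fit <- select_by_aic(list(
  fit_mrds(events, key = "hr", w = 300, mr_formula = ~ distance_m * observer),
  fit_mrds(events, key = "hn", w = 300, mr_formula = ~ distance_m * observer)))
fit
#> <detection_fit mrds> key=hr w=300 m, n=166, logLik=-1051.88, AIC=2115.75
#>   MR trackline p(0): observer_1=0.884, observer_2=0.828 (combined 0.980)
round(unlist(average_detection_probability(fit, B = 99, seed = 3)[c("p", "cv")]), 3)
#>     p    cv
#> 0.554 0.119

# effective effort -> 10-km cell-days -> GAM selection with CV
seg   <- transfer_detection(fit, eff$segments)
cells <- summarize_grid(segment_to_cells(seg, grid), events, seg, env)
scr   <- screen_collinearity(cells, c("sst", "front_z", "dshore_km", "chla"))
sel   <- select_sdm(cells, enumerate_candidates(
  c("sst", "front_z", "dshore_km", "chla"), scr), cv_k = 10, seed = 4)
sel$best
#> <sdm_fit> offset(log(effort)) + front_z x sst + sst + front_z + chla
#>   n=720 (149 presences), AIC=675.4, deviance explained=11.0%
```

The fitted `p̄ = 0.554` is the average probability that an animal present
inside the 300-m strip was seen by at least one team (truth here:
`p(0) = 1 − 0.2·0.3 = 0.94` times the mean of the hazard-rate key); its CV
comes from a 99-replicate bootstrap over events. The selected model
recovers the simulated dome in SST plus the frontal and nearshore
enrichment. From there, `predict_surface()`, `weighted_ensemble()`,
`external_z_validation()`, `centroid_series()`, `fit_sarima()` and
`forecast_sarima()` complete the analysis; `autoplot()` methods draw each
result type.

The whole chain runs as one command from a YAML config:

```r
run_pipeline(demo_config(), outdir = "my_run")
# or from a shell:
#   Rscript inst/scripts/aerialsdm run-all --config cfg.yaml --outdir my_run
```

writing per-stage CSVs, a run log, and a machine-readable `report.json`
(detection p̄/CV, model AIC and deviance explained, CV AUC, validation
t-test, SARIMA coefficients).

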