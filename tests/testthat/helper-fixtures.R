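# Shared fixtures built in code.

# sample detected perpendicular distances: animals placed uniformly in
# [0, w], retained with probability g(x) (rejection sampling)
sample_detected_distances <- function(n, key = "hn", sigma = 150, shape = NULL,
                                      w = 300, seed = 1) {
  withr::with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::runif(2 * n, 0, w)
      keep <- stats::runif(2 * n) < detection_key(x, key, sigma, shape)
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  })
}

# closed-form average detection probability for a half-normal key, p(0)=1:
# p = sigma * sqrt(pi/2) * erf(w / (sigma*sqrt(2))) / w
hn_pbar <- function(sigma, w) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  sigma * sqrt(pi / 2) * erf(w / (sigma * sqrt(2))) / w
}

# simulated dual-observer event table: uniform placement in [0, w], two
# observers detecting independently with p0 * g(x); returns events seen by
# at least one observer
simulate_mrds_events <- function(n_place, p0 = c(0.8, 0.7), key = "hn",
                                 sigma = 150, shape = NULL, w = 300, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::runif(n_place, 0, w)
    g <- detection_key(x, key, sigma, shape)
    d1 <- stats::runif(n_place) < p0[1] * g
    d2 <- stats::runif(n_place) < p0[2] * g
    tibble::tibble(distance_m = x, observer_1 = d1, observer_2 = d2)[d1 | d2, ]
  })
}

# tiny surveyed landscape with perfect detection: returns a cell table with
# a known dome-shaped SST response (optimum sst_opt) for GAM recovery tests
simulate_dome_cells <- function(seed, nx = 14, ny = 20, n_steps = 18,
                                density = 0.2, sst_opt = 23,
                                noise_covariate = TRUE) {
  g <- grid_spec(cell_km = 10, nx = nx, ny = ny, lat0 = 25)
  env <- generate_environment(
    g, n_steps,
    season_params(period = 12, sst_south = 26, ns_gradient = 1.2,
                  amplitude = 4, peak_step = 7),
    seed = seed)
  env <- compute_front_z(env)
  truth <- occurrence_model(intercept = 0.5, sst_opt = sst_opt, sst_width = 3,
                            betas = c(front_z = 1.5, dshore_km = -0.015))
  p_true <- true_probability_surface(env, truth)
  tl <- make_tracklines(g, steps = seq_len(n_steps), spacing_km = 30)
  sc <- survey_scenario(
    tl, record_interval_s = 120, strip_m = 300,
    teams = "forward",
    detection = detection_truth("hn", sigma_m = 1e6, p0 = c(forward = 1)),
    density_per_km2 = density, seed = seed + 1000)
  sv <- simulate_survey(env, p_true, sc)
  seg <- dplyr::mutate(sv$effort, p_detect = 1,
                       effort_m2 = effective_effort(length_m, 1, 300))
  alloc <- segment_to_cells(seg, g)
  ct <- suppressWarnings(summarize_grid(alloc, sv$sightings, seg, env))
  if (noise_covariate) {
    ct$noise <- withr::with_seed(seed + 2000, stats::rnorm(nrow(ct)))
  }
  list(cells = ct, env = env, p_true = p_true, grid = g, truth = truth)
}

# small prediction surface with an attached grid, built directly
toy_surface <- function(p_fun, steps = 1:3, nx = 6, ny = 8, se = 0.1) {
  g <- grid_spec(cell_km = 10, nx = nx, ny = ny, lat0 = 25)
  cells <- grid_cells(g)
  d <- tidyr::expand_grid(step = steps, cells) |>
    dplyr::mutate(p = p_fun(x_km, y_km, step), se = se,
                  masked = FALSE, extrapolated = FALSE) |>
    dplyr::select(step, cell, lat, p, se, masked, extrapolated,
                  x_km, y_km)
  attr(d, "grid") <- g
  class(d) <- c("prediction_surface", class(d))
  d
}
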