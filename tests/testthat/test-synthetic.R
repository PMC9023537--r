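test_that("environment generation is deterministic and seasonally structured", {
  g <- grid_spec(cell_km = 10, nx = 8, ny = 10, lat0 = 25)
  e1 <- generate_environment(g, 6, season_params(period = 12), seed = 7)
  e2 <- generate_environment(g, 6, season_params(period = 12), seed = 7)
  expect_identical(e1, e2)
  e3 <- generate_environment(g, 6, season_params(period = 12), seed = 8)
  expect_false(identical(e1$sst, e3$sst))

  # frozen seasons: amplitude 0 makes SST constant across steps per cell
  e0 <- generate_environment(g, 6, season_params(amplitude = 0), seed = 7)
  per_cell_sd <- tapply(e0$sst, e0$cell, sd)
  expect_true(all(per_cell_sd == 0))

  # depth increases monotonically offshore along every row
  one <- dplyr::filter(e1, step == 1)
  for (row in split(one, one$iy)) {
    expect_true(all(diff(row$depth[order(row$ix)]) > 0))
  }
  expect_true(all(e1$depth >= 0))
  expect_true(all(e1$slope >= 0))
  expect_true(all(is.finite(e1$sst)))
})

test_that("a sharp front places the maximum SST gradient on the front line", {
  g <- grid_spec(cell_km = 10, nx = 10, ny = 6, lat0 = 25)
  sp <- season_params(front_x_km = 45, front_contrast = 5, noise_sd = 0,
                      ns_gradient = 0, amplitude = 0)
  env <- generate_environment(g, 1, sp, seed = 1)
  # independent finite-difference oracle for the gradient argmax column
  m <- matrix(env$sst[order(env$iy, env$ix)], nrow = g$ny, byrow = TRUE)
  gx <- abs(m[, -1] - m[, -ncol(m)])
  step_col <- which.max(colSums(gx))      # step between centres 45 | 55 km
  expect_equal(step_col, 5L)
  fz <- compute_front_z(env)
  top <- dplyr::filter(fz, front_z == 1)
  # central differences straddle the step: max-gradient cells flank the line
  expect_true(all(top$x_km %in% c(45, 55)))
})

test_that("true probability surface honors the link and errors on missing layers", {
  g <- grid_spec(nx = 6, ny = 6, lat0 = 25)
  env <- generate_environment(g, 2, season_params(), seed = 2)
  flat <- occurrence_model(intercept = 0, sst_opt = 0, sst_width = Inf,
                           betas = numeric(0))
  p <- true_probability_surface(env, flat)
  expect_true(all(p$p == 0.5))

  dome <- occurrence_model(intercept = 0, sst_opt = 23, sst_width = 2,
                           betas = numeric(0))
  # sweep SST directly: argmax must sit at the dome centre
  sweep_env <- tibble::tibble(step = 1L, cell = seq_along(seq(10, 32, 0.25)),
                              sst = seq(10, 32, 0.25))
  ps <- true_probability_surface(sweep_env, dome)
  expect_equal(sweep_env$sst[which.max(ps$p)], 23)

  low <- occurrence_model(intercept = -30, sst_opt = 23, sst_width = 2,
                          betas = numeric(0))
  pl <- true_probability_surface(env, low)
  expect_true(all(pl$p < 1e-8) && all(pl$p > 0))

  needs_fz <- occurrence_model(betas = c(front_z = 1))
  expect_error(true_probability_surface(env, needs_fz), "front_z")
})

test_that("survey simulation is deterministic and honors degenerate cases", {
  g <- grid_spec(nx = 8, ny = 8, lat0 = 25)
  env <- generate_environment(g, 2, season_params(period = 12), seed = 1)
  p <- true_probability_surface(env, occurrence_model(betas = c(dshore_km = -0.01)))
  tl <- make_tracklines(g, 1:2, spacing_km = 40)
  sc <- survey_scenario(tl, density_per_km2 = 0.5, seed = 11,
                        record_interval_s = 60)
  s1 <- simulate_survey(env, p, sc)
  s2 <- simulate_survey(env, p, sc)
  expect_identical(s1$sightings, s2$sightings)
  expect_identical(s1$truth, s2$truth)

  # p == 0 everywhere: no placements, no sightings
  p0 <- dplyr::mutate(p, p = 0)
  s0 <- simulate_survey(env, p0, sc)
  expect_identical(nrow(s0$truth), 0L)
  expect_identical(nrow(s0$sightings), 0L)

  # perfect detection: every placed animal appears in both team tables
  sc_perfect <- survey_scenario(
    tl, density_per_km2 = 0.5, seed = 12, record_interval_s = 60,
    detection = detection_truth("hn", sigma_m = 1e9,
                                p0 = c(forward = 1, aft = 1)))
  sp <- simulate_survey(env, p, sc_perfect)
  expect_true(all(sp$truth$det_forward) && all(sp$truth$det_aft))
  expect_equal(sum(sp$sightings$team == "forward"), nrow(sp$truth))
  expect_equal(sum(sp$sightings$team == "aft"), nrow(sp$truth))

  expect_error(simulate_survey(env, p, survey_scenario(tl[0, ], seed = 1)),
               "tracklines")
})

test_that("recorded angles back-convert exactly to placement distances", {
  g <- grid_spec(nx = 8, ny = 8, lat0 = 25)
  env <- generate_environment(g, 1, season_params(), seed = 3)
  p <- true_probability_surface(env, occurrence_model(betas = numeric(0)))
  tl <- make_tracklines(g, 1, spacing_km = 30)
  sv <- simulate_survey(env, p, survey_scenario(tl, density_per_km2 = 1,
                                                seed = 5, record_interval_s = 60))
  joined <- dplyr::inner_join(sv$sightings, sv$truth[, c("animal", "distance_m")],
                              by = "animal")
  back <- angle_to_distance(joined$theta_deg, joined$altitude_m)
  expect_true(all(abs(back - joined$distance_m) /
                    pmax(joined$distance_m, 1e-12) <= 1e-9 |
                    joined$distance_m == 0))
})

test_that("sighting counts follow the thinned Poisson expectation", {
  # 1000 km of effort, density 0.01/km^2, 600-m strip, p = 1:
  # expected sightings = 1000 * 0.01 * 0.6 = 6
  g <- grid_spec(cell_km = 10, nx = 10, ny = 10, lat0 = 25)
  env <- generate_environment(g, 10, season_params(amplitude = 0), seed = 1)
  p1 <- dplyr::mutate(
    true_probability_surface(env, occurrence_model(betas = numeric(0))), p = 1)
  tl <- make_tracklines(g, 1:10, spacing_km = 100)   # 1 transect x 100 km x 10
  counts <- vapply(1:200, function(s) {
    sc <- survey_scenario(tl, strip_m = 300, density_per_km2 = 0.01,
                          record_interval_s = 120, teams = "forward",
                          detection = detection_truth("hn", 1e9,
                                                      p0 = c(forward = 1)),
                          seed = s)
    nrow(simulate_survey(env, p1, sc)$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 6), 3 * sqrt(6 / 200))
})

test_that("empirical detection frequency converges to the truth key", {
  # detected-distance ECDF vs the key-implied CDF, sup-difference < 0.05
  w <- 600
  for (key in c("hn", "hr")) {
    x <- sample_detected_distances(1e4, key, sigma = 150,
                                   shape = if (key == "hr") 2.5,
                                   w = w, seed = 42)
    shape <- if (key == "hr") 2.5 else NULL
    mu <- aerialsdm:::key_integral(key, 150, shape, w)
    grid <- seq(0, w, length.out = 200)
    cdf <- vapply(grid, function(u) aerialsdm:::key_integral(key, 150, shape, u),
                  numeric(1)) / mu
    emp <- stats::ecdf(x)(grid)
    expect_lt(max(abs(emp - cdf)), 0.05)
  }
})
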