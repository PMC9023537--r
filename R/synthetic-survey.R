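#' Ground-truth detection process for simulated surveys
#'
#' @param key `"hr"` (hazard-rate, the default, giving the broad shoulder
#'   typical of aerial surveys) or `"hn"` (half-normal).
#' @param sigma_m Key scale in metres.
#' @param shape Hazard-rate shape (> 1 gives a shoulder).
#' @param p0 Named vector of trackline (distance-zero) detection
#'   probabilities per team, e.g. `c(forward = 0.8, aft = 0.7)`. A
#'   single-team survey uses one element.
#' @return A list of class `detection_truth`.
#' @export
detection_truth <- function(key = c("hr", "hn"), sigma_m = 130, shape = 2.5,
                            p0 = c(forward = 0.8, aft = 0.7)) {
  key <- match.arg(key)
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must lie in [0, 1].", call. = FALSE)
  if (is.null(names(p0))) stop("`p0` must be named by team.", call. = FALSE)
  structure(list(key = key, sigma_m = sigma_m, shape = shape, p0 = p0),
            class = "detection_truth")
}

#' East-west transect design over the grid
#'
#' Lays evenly spaced cross-shelf transects for each requested step, the
#' standard design for shelf aerial surveys.
#'
#' @param grid A [grid_spec()].
#' @param steps Integer vector of time steps on which transects are flown.
#' @param spacing_km Along-shore spacing between transects.
#' @param x_from_km,x_to_km Cross-shelf start and end of each transect
#'   (defaults: full grid width).
#' @return A tibble with one row per transect: `step`, `transect`, `x0`,
#'   `y0`, `x1`, `y1` (km).
#' @export
make_tracklines <- function(grid, steps, spacing_km = 20,
                            x_from_km = 0, x_to_km = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(x_to_km)) x_to_km <- grid$nx * grid$cell_km
  ys <- seq(spacing_km / 2, grid$ny * grid$cell_km - spacing_km / 2,
            by = spacing_km)
  tidyr::expand_grid(step = as.integer(steps), y = ys) |>
    dplyr::group_by(.data$step) |>
    dplyr::mutate(transect = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$step, .data$transect,
                     x0 = x_from_km, y0 = .data$y, x1 = x_to_km, y1 = .data$y)
}

#' Describe a simulated aerial survey
#'
#' @param tracklines Tibble of transects (`step`, `x0`, `y0`, `x1`, `y1` in
#'   km), e.g. from [make_tracklines()].
#' @param altitude_m Flight altitude (m); the default is the 182 m typical of
#'   twin-engine marine-mammal survey aircraft.
#' @param airspeed_kmh Ground speed (km/h).
#' @param record_interval_s Effort logging interval (s); one effort segment
#'   per interval.
#' @param teams Character vector of observer teams; two teams give a
#'   dual-observer (mark-recapture) survey, one team a single-platform one.
#' @param detection A [detection_truth()].
#' @param strip_m Half-strip width simulated on each side of the trackline
#'   (m); animals are placed out to this distance.
#' @param density_per_km2 Baseline animal density at occurrence probability 1.
#' @param angle_noise_sd_deg,time_noise_sd_s SD of measurement noise added to
#'   recorded clinometer angles / timestamps. Defaults 0: recorded angles then
#'   back-convert exactly to placement distances.
#' @param beaufort_probs Probabilities of Beaufort states 0..length-1 drawn
#'   per segment.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param survey_id Label stamped on all output rows.
#' @return A list of class `survey_scenario`.
#' @export
survey_scenario <- function(tracklines, altitude_m = 182, airspeed_kmh = 185,
                            record_interval_s = 10,
                            teams = c("forward", "aft"),
                            detection = detection_truth(),
                            strip_m = 600, density_per_km2 = 0.02,
                            angle_noise_sd_deg = 0, time_noise_sd_s = 0,
                            beaufort_probs = c(.1, .2, .3, .25, .15),
                            seed = 1L, survey_id = "synthetic") {
  if (altitude_m <= 0) stop("`altitude_m` must be positive.", call. = FALSE)
  stopifnot(inherits(detection, "detection_truth"))
  if (!all(teams %in% names(detection$p0))) {
    stop("every team needs a trackline probability in `detection$p0`.",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "survey_scenario")
}

#' Simulate a dual-observer aerial survey over a known occurrence surface
#'
#' Animals are placed along each transect by a thinned Poisson point process
#' with intensity `density_per_km2 * p(cell)`; each animal within the
#' simulated strip receives independent per-team detection draws from the
#' truth detection model (`p0[team] * g(distance)`), and detected animals get
#' a clinometer angle `theta = atan(distance / altitude)` recorded. The truth
#' ledger retains every placement and which team(s) detected it.
#'
#' @param env An `env_stack` (used for per-segment condition context).
#' @param p_surface Output of [true_probability_surface()]; must cover every
#'   step flown.
#' @param scenario A [survey_scenario()].
#' @return A list of class `synthetic_survey` with tibbles `effort`
#'   (segments), `sightings` (one row per team x detection) and `truth` (all
#'   placements).
#' @export
simulate_survey <- function(env, p_surface, scenario) {
  stopifnot(inherits(scenario, "survey_scenario"))
  grid <- attr(env, "grid")
  if (is.null(grid)) stop("`env` must carry its grid attribute.", call. = FALSE)
  tl <- scenario$tracklines
  if (nrow(tl) == 0) stop("scenario has no tracklines.", call. = FALSE)
  len_km <- sqrt((tl$x1 - tl$x0)^2 + (tl$y1 - tl$y0)^2)
  if (any(len_km <= 0)) stop("zero-length trackline.", call. = FALSE)
  ext_x <- grid$nx * grid$cell_km; ext_y <- grid$ny * grid$cell_km
  if (any(tl$x0 < 0 | tl$x1 > ext_x | tl$x1 < 0 | tl$x0 > ext_x |
            tl$y0 < 0 | tl$y0 > ext_y | tl$y1 < 0 | tl$y1 > ext_y)) {
    stop("tracklines extend outside the grid.", call. = FALSE)
  }

  seg_km <- scenario$airspeed_kmh / 3600 * scenario$record_interval_s
  withr::with_seed(as.integer(scenario$seed), {
    segs <- purrr::pmap(
      dplyr::mutate(tl, .len = len_km, .tid = dplyr::row_number()),
      function(step, x0, y0, x1, y1, .len, .tid, ...) {
        n <- max(1L, ceiling(.len / seg_km))
        brk <- seq(0, .len, length.out = n + 1L)
        f0 <- utils::head(brk, -1L) / .len
        f1 <- brk[-1L] / .len
        tibble::tibble(
          step = step, transect = .tid,
          x_start = x0 + (x1 - x0) * f0, y_start = y0 + (y1 - y0) * f0,
          x_end = x0 + (x1 - x0) * f1, y_end = y0 + (y1 - y0) * f1,
          length_m = (brk[-1L] - utils::head(brk, -1L)) * 1000
        )
      }) |>
      purrr::list_rbind() |>
      dplyr::mutate(
        segment = dplyr::row_number(),
        heading = (atan2(.data$x_end - .data$x_start,
                         .data$y_end - .data$y_start) * 180 / pi) %% 360,
        altitude_m = scenario$altitude_m,
        beaufort = sample(seq_along(scenario$beaufort_probs) - 1L,
                          dplyr::n(), TRUE, scenario$beaufort_probs),
        cloud = sample(0:8, dplyr::n(), TRUE),
        glare_int = sample(0:2, dplyr::n(), TRUE, c(.5, .3, .2)),
        glare_cov = round(.data$glare_int * stats::runif(dplyr::n(), 0, .5), 2),
        turbidity = sample(0:2, dplyr::n(), TRUE, c(.6, .3, .1)),
        on_effort = TRUE, survey_id = scenario$survey_id
      )

    # cumulative time along each day's flight
    segs <- segs |>
      dplyr::group_by(.data$step) |>
      dplyr::mutate(t_start_s = cumsum(dplyr::lag(.data$length_m, default = 0)) /
                      (scenario$airspeed_kmh / 3.6)) |>
      dplyr::ungroup()

    mid_cell <- locate_cell(grid,
                            (segs$x_start + segs$x_end) / 2,
                            (segs$y_start + segs$y_end) / 2)
    segs$cell <- mid_cell
    pmap <- dplyr::select(p_surface, "step", "cell", "p")
    segs <- dplyr::left_join(segs, pmap, by = c("step", "cell"))
    if (anyNA(segs$p)) {
      stop("p_surface does not cover every surveyed step/cell.", call. = FALSE)
    }

    strip_km2 <- segs$length_m / 1000 * (2 * scenario$strip_m / 1000)
    n_anim <- stats::rpois(nrow(segs), scenario$density_per_km2 * segs$p * strip_km2)

    place <- segs[rep(seq_len(nrow(segs)), n_anim), ] |>
      dplyr::mutate(
        animal = dplyr::row_number(),
        distance_m = stats::runif(dplyr::n(), 0, scenario$strip_m),
        side = sample(c("left", "right"), dplyr::n(), TRUE),
        size = 1L,
        along = stats::runif(dplyr::n()),
        x_km = .data$x_start + (.data$x_end - .data$x_start) * .data$along,
        y_km = .data$y_start + (.data$y_end - .data$y_start) * .data$along,
        time_s = .data$t_start_s +
          .data$along * .data$length_m / (scenario$airspeed_kmh / 3.6)
      )

    det <- scenario$detection
    g <- detection_key(place$distance_m, det$key, det$sigma_m, det$shape)
    truth <- place
    sightings <- list()
    for (team in scenario$teams) {
      pdet <- det$p0[[team]] * g
      hit <- stats::runif(nrow(place)) < pdet
      truth[[paste0("det_", team)]] <- hit
      theta <- atan(place$distance_m / scenario$altitude_m) * 180 / pi
      if (scenario$angle_noise_sd_deg > 0) {
        theta <- pmin(pmax(theta + stats::rnorm(length(theta), 0,
                                                scenario$angle_noise_sd_deg), 0), 89.9)
      }
      tt <- place$time_s
      if (scenario$time_noise_sd_s > 0) {
        tt <- tt + stats::rnorm(length(tt), 0, scenario$time_noise_sd_s)
      }
      idx <- which(hit)
      sightings[[team]] <- tibble::tibble(
        survey_id = scenario$survey_id, team = team,
        step = place$step[idx], segment = place$segment[idx],
        animal = place$animal[idx],
        time_s = tt[idx], theta_deg = theta[idx], side = place$side[idx],
        size = place$size[idx], altitude_m = scenario$altitude_m,
        beaufort = place$beaufort[idx], cloud = place$cloud[idx],
        glare_int = place$glare_int[idx], glare_cov = place$glare_cov[idx],
        turbidity = place$turbidity[idx], on_effort = TRUE,
        x_km = place$x_km[idx], y_km = place$y_km[idx]
      )
    }
    sightings <- purrr::list_rbind(sightings)

    truth <- dplyr::select(truth, "animal", "step", "transect", "segment",
                           "cell", "x_km", "y_km", "distance_m", "side",
                           "size", dplyr::starts_with("det_"))
    effort <- dplyr::select(segs, "survey_id", "segment", "step", "transect",
                            "cell", "x_start", "y_start", "x_end", "y_end",
                            "length_m", "heading", "altitude_m", "beaufort",
                            "cloud", "glare_int", "glare_cov", "turbidity",
                            "t_start_s", "on_effort")
    structure(list(effort = effort, sightings = sightings, truth = truth,
                   scenario = scenario),
              class = "synthetic_survey")
  })
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("<synthetic_survey '%s'> %d segments, %d placements, %d sighting rows\n",
              x$scenario$survey_id, nrow(x$effort), nrow(x$truth),
              nrow(x$sightings)))
  invisible(x)
}
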