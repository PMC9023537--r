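#' Seasonal forcing and field parameters for synthetic environments
#'
#' Collects the knobs that shape the simulated covariate fields. Defaults
#' describe a subtropical western-boundary shelf: sea-surface temperature
#' (SST) warmest in the south and in late summer, a sharp offshore thermal
#' front at the shelf edge, chlorophyll enriched nearshore, a northward jet
#' offshore, and a monotone shelf-to-slope bathymetry.
#'
#' @param period Length of the seasonal cycle in steps. Use 365 when a step
#'   is a day, 12 when a step is a monthly mean.
#' @param sst_south Annual-mean SST (deg C) at the southern grid edge.
#' @param ns_gradient Meridional SST decrease, deg C per 100 km northward.
#' @param amplitude Seasonal SST half-range (deg C); 0 freezes the seasons.
#' @param peak_step Step (phase) at which the seasonal cycle peaks.
#' @param front_x_km Cross-shelf position of the thermal front; cells with
#'   centres offshore of this line are warmer by `front_contrast`.
#' @param front_contrast SST step across the front (deg C).
#' @param noise_sd SD of the static (per-cell, not per-step) SST texture.
#' @param depth_max Depth (m) reached at the offshore grid edge.
#' @param shelf_exp Exponent of the cross-shelf depth profile; depth grows as
#'   `depth_max * (x / xmax)^shelf_exp`, monotone offshore for any
#'   positive exponent.
#' @param chla_coast Nearshore chlorophyll-a level (mg/m^3).
#' @param chla_scale e-folding scale (km) of the offshore chlorophyll decay.
#' @param pp_scale Multiplier converting chlorophyll to primary productivity
#'   (mg C m^-2 day^-1).
#' @param jet_x_km,jet_width_km,v_max Position, width and peak speed (m/s) of
#'   the northward current jet.
#' @param wave_base,wave_amp Mean and seasonal half-range of wave height (m).
#' @param interannual_frac SD of the step-wide SST anomaly as a fraction of
#'   `amplitude` (default 0.1): real seasonal cycles never repeat exactly,
#'   and this keeps monthly series away from perfectly periodic degeneracy.
#'   Zero amplitude implies zero anomaly, so a frozen-season run is exactly
#'   constant in time.
#' @return A list of class `season_params`.
#' @export
season_params <- function(period = 365, sst_south = 25, ns_gradient = 3,
                          amplitude = 4, peak_step = 210,
                          front_x_km = 65, front_contrast = 2, noise_sd = 0.3,
                          depth_max = 3000, shelf_exp = 1.8,
                          chla_coast = 5, chla_scale = 60, pp_scale = 300,
                          jet_x_km = 105, jet_width_km = 35, v_max = 0.6,
                          wave_base = 1, wave_amp = 0.4,
                          interannual_frac = 0.1) {
  structure(as.list(environment()), class = "season_params")
}

#' Generate a synthetic environmental covariate stack
#'
#' Builds a cell-by-step table of the covariates the distribution models use:
#' `sst` (with a north-south gradient, a sinusoidal seasonal cycle, a sharp
#' cross-shelf front and static spatial texture), `chla`, `pp`, `depth`
#' (positive down, increasing monotonically offshore), `slope` (degrees, from
#' the cross-shelf depth difference), `vnorth` and `waveheight`. The stack is
#' deterministic given `seed`.
#'
#' @param grid A [grid_spec()].
#' @param n_steps Number of time steps (days, or months for monthly means).
#' @param season A [season_params()] list.
#' @param seed Integer seed controlling the static noise fields.
#' @return A tibble of class `env_stack` with one row per cell and step and
#'   the grid attached as attribute `grid`.
#' @examples
#' env <- generate_environment(grid_spec(nx = 6, ny = 5), n_steps = 4, seed = 1)
#' dplyr::count(env, step)
#' @export
generate_environment <- function(grid, n_steps, season = season_params(),
                                 seed = 1L) {
  if (!inherits(grid, "grid_spec")) {
    stop("`grid` must be a grid_spec.", call. = FALSE)
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("`n_steps` must be a positive integer.", call. = FALSE)
  }
  if (!inherits(season, "season_params")) {
    stop("`season` must come from season_params().", call. = FALSE)
  }
  sp <- season
  cells <- grid_cells(grid)
  xmax <- grid$nx * grid$cell_km

  rng <- withr::with_seed(as.integer(seed), {
    n <- nrow(cells)
    list(
      static = tibble::tibble(
        cell = cells$cell,
        sst_tex = stats::rnorm(n, 0, sp$noise_sd),
        chla_tex = stats::rlnorm(n, 0, 0.25),
        v_tex = stats::rnorm(n, 0, 0.05),
        wave_tex = stats::rnorm(n, 0, 0.1)
      ),
      # step-wide SST anomaly: the seasonal cycle never repeats exactly
      anomaly = stats::rnorm(n_steps, 0, sp$amplitude * sp$interannual_frac)
    )
  })
  static <- rng$static

  cells <- dplyr::left_join(cells, static, by = "cell") |>
    dplyr::mutate(
      depth = sp$depth_max * (.data$x_km / xmax)^sp$shelf_exp,
      # slope from the cross-shelf depth increment over one cell width
      slope = atan((sp$depth_max / 1000) *
                     ((.data$x_km / xmax)^sp$shelf_exp -
                        (pmax(.data$x_km - grid$cell_km, 0) / xmax)^sp$shelf_exp) /
                     grid$cell_km) * 180 / pi,
      chla0 = sp$chla_coast * exp(-.data$dshore_km / sp$chla_scale) * .data$chla_tex,
      vnorth = sp$v_max * exp(-((.data$x_km - sp$jet_x_km) / sp$jet_width_km)^2) +
        .data$v_tex
    )

  steps <- tibble::tibble(
    step = seq_len(n_steps),
    season_term = sp$amplitude * cos(2 * pi * (.data$step - sp$peak_step) / sp$period) +
      rng$anomaly
  )

  env <- tidyr::expand_grid(steps, cells) |>
    dplyr::mutate(
      sst = sp$sst_south - sp$ns_gradient * .data$y_km / 100 +
        .data$season_term +
        sp$front_contrast * (.data$x_km > sp$front_x_km) +
        .data$sst_tex,
      chla = .data$chla0 * (1 + 0.3 * cos(2 * pi * (.data$step - sp$peak_step / 2) / sp$period)),
      pp = sp$pp_scale * .data$chla^0.9,
      waveheight = pmax(
        sp$wave_base - sp$wave_amp * cos(2 * pi * (.data$step - sp$peak_step) / sp$period) +
          .data$wave_tex, 0.05)
    ) |>
    dplyr::select("step", "cell", "ix", "iy", "x_km", "y_km", "lat", "dshore_km",
                  "sst", "chla", "pp", "depth", "slope", "vnorth", "waveheight")

  attr(env, "grid") <- grid
  attr(env, "season") <- sp
  class(env) <- c("env_stack", class(env))
  env
}

#' Known occurrence model used as simulation ground truth
#'
#' Probability of occurrence follows a logistic model with a Gaussian-shaped
#' (dome) response to SST plus linear terms in any other environment layers:
#' `logit(p) = intercept - ((sst - sst_opt)/sst_width)^2 + sum(beta_j * layer_j)`.
#'
#' @param intercept Intercept on the logit scale.
#' @param sst_opt Thermal optimum (deg C) at the dome centre.
#' @param sst_width Dome width (deg C); larger is flatter.
#' @param betas Named numeric vector of linear slopes on additional layers
#'   (names must match environment columns, e.g. `c(front_z = 1.5,
#'   dshore_km = -0.02)`). May be empty.
#' @return An object of class `occurrence_model`.
#' @export
occurrence_model <- function(intercept = 0.5, sst_opt = 23, sst_width = 3,
                             betas = c(front_z = 1.5, dshore_km = -0.015)) {
  if (length(betas) && is.null(names(betas))) {
    stop("`betas` must be named by environment layer.", call. = FALSE)
  }
  structure(list(intercept = intercept, sst_opt = sst_opt,
                 sst_width = sst_width, betas = betas),
            class = "occurrence_model")
}

#' Evaluate the true probability-of-occurrence surface
#'
#' @param env An `env_stack` tibble (see [generate_environment()]); must
#'   contain every layer named in `model$betas` (run [compute_front_z()]
#'   first if the model uses `front_z`).
#' @param model An [occurrence_model()].
#' @return A tibble with the env key columns and a `p` column in (0, 1).
#' @export
true_probability_surface <- function(env, model) {
  stopifnot(inherits(model, "occurrence_model"))
  need <- c("sst", names(model$betas))
  missing <- setdiff(need, names(env))
  if (length(missing)) {
    stop("environment stack is missing layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept -
    ((env$sst - model$sst_opt) / model$sst_width)^2
  for (nm in names(model$betas)) {
    eta <- eta + model$betas[[nm]] * env[[nm]]
  }
  out <- dplyr::select(tibble::as_tibble(env), dplyr::any_of(
    c("step", "cell", "ix", "iy", "x_km", "y_km", "lat", "dshore_km", "depth")))
  out$p <- stats::plogis(eta)
  attr(out, "grid") <- attr(env, "grid")
  out
}
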