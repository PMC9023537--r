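#' Standardized SST frontal gradient (Front-Z)
#'
#' Computes the magnitude of the horizontal SST gradient by central
#' differences (one-sided at grid edges) and standardizes it by the maximum
#' over the model domain within each time step, so values lie in `[0, 1]`
#' and the strongest front each day scores exactly 1. Standardizing to the
#' daily maximum keeps well-defined fronts identifiable even when the whole
#' domain warms seasonally. A uniform field (zero gradient everywhere) is
#' defined as all zeros.
#'
#' @param env An `env_stack` tibble with `step`, `ix`, `iy`, `sst` and its
#'   grid attribute (or any tibble with those columns plus `cell`).
#' @return `env` with a `front_z` column appended.
#' @export
compute_front_z <- function(env) {
  stopifnot(all(c("step", "ix", "iy", "sst") %in% names(env)))
  grid <- attr(env, "grid")
  cell_km <- if (!is.null(grid)) grid$cell_km else 1
  out <- dplyr::group_by(tibble::as_tibble(env), .data$step) |>
    dplyr::group_modify(function(d, key) {
      nx <- max(d$ix); ny <- max(d$iy)
      if (nx < 2 || ny < 2) stop("front gradient needs at least 2x2 cells.",
                                 call. = FALSE)
      m <- matrix(NA_real_, nrow = ny, ncol = nx)
      m[cbind(d$iy, d$ix)] <- d$sst
      if (all(is.na(m))) stop("all-masked SST raster.", call. = FALSE)
      gx <- m; gy <- m
      # central differences, one-sided at the edges
      gx[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * cell_km)
      gx[, 1] <- (m[, 2] - m[, 1]) / cell_km
      gx[, nx] <- (m[, nx] - m[, nx - 1]) / cell_km
      gy[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * cell_km)
      gy[1, ] <- (m[2, ] - m[1, ]) / cell_km
      gy[ny, ] <- (m[ny, ] - m[ny - 1, ]) / cell_km
      mag <- sqrt(gx^2 + gy^2)
      mx <- max(mag, na.rm = TRUE)
      fz <- if (mx > 0) mag / mx else mag * 0
      d$front_z <- fz[cbind(d$iy, d$ix)]
      d
    }) |>
    dplyr::ungroup()
  attr(out, "grid") <- grid
  attr(out, "season") <- attr(env, "season")
  class(out) <- class(env)
  out
}

#' Allocate trackline segments to grid cells
#'
#' Splits each straight segment at every cell boundary it crosses and
#' allocates its length among the intersected cells by geometric overlap, so
#' the summed allocation equals the segment length.
#'
#' @param segments Tibble with `segment`, `x_start`, `y_start`, `x_end`,
#'   `y_end` (km) and `length_m`.
#' @param grid A [grid_spec()].
#' @return A tibble `segment`, `cell`, `alloc_m`. Segments (or pieces)
#'   falling outside the grid are skipped; the skipped length is attached as
#'   attribute `skipped_m`.
#' @export
segment_to_cells <- function(segments, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  seg <- tibble::as_tibble(segments)
  ck <- grid$cell_km
  skipped <- 0
  res <- purrr::pmap(
    list(seg$segment, seg$x_start, seg$y_start, seg$x_end, seg$y_end,
         seg$length_m),
    function(id, x0, y0, x1, y1, len) {
      # parameter values where the segment crosses cell boundary lines
      tx <- if (x1 != x0) {
        k <- seq(ceiling(min(x0, x1) / ck), floor(max(x0, x1) / ck)) * ck
        (k - x0) / (x1 - x0)
      } else numeric(0)
      ty <- if (y1 != y0) {
        k <- seq(ceiling(min(y0, y1) / ck), floor(max(y0, y1) / ck)) * ck
        (k - y0) / (y1 - y0)
      } else numeric(0)
      ts <- sort(unique(c(0, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1], 1)))
      tm <- (utils::head(ts, -1) + ts[-1]) / 2
      cells <- locate_cell(grid, x0 + (x1 - x0) * tm, y0 + (y1 - y0) * tm)
      alloc <- diff(ts) * len
      ok <- !is.na(cells)
      if (!all(ok)) skipped <<- skipped + sum(alloc[!ok])
      if (!any(ok)) return(NULL)
      tibble::tibble(segment = id, cell = cells[ok], alloc_m = alloc[ok])
    })
  out <- purrr::list_rbind(purrr::compact(res))
  if (nrow(out)) {
    out <- dplyr::summarise(out, alloc_m = sum(.data$alloc_m),
                            .by = c("segment", "cell"))
  }
  attr(out, "skipped_m") <- skipped
  out
}

#' Summarize sightings, effort and covariates to cell-day records
#'
#' Builds the model-ready table: per cell and step, sightings are summed,
#' effective effort (m^2) is summed (each segment's effort apportioned by
#' allocated length), environmental covariates are averaged (weighted by
#' allocated trackline length by default), and the maximum bathymetric slope
#' along the surveyed track is retained. Cells with zero effort are excluded
#' from model input; sightings falling in a cell-day without effort are
#' dropped with a warning.
#'
#' @param alloc Output of [segment_to_cells()].
#' @param sightings Tibble with `step` and either `cell` or `x_km`/`y_km`
#'   (plus optional `size`); one row per sighting event.
#' @param segments Effort tibble with `segment`, `step`, `length_m` and
#'   `effort_m2` (e.g. from [transfer_detection()]).
#' @param env Environment stack providing per cell-step covariates (any of
#'   `sst`, `front_z`, `chla`, `pp`, `depth`, `slope`, `vnorth`,
#'   `waveheight`, `dshore_km`, `lat`).
#' @param weighted Weight covariate means by allocated length (default) or
#'   use unweighted means.
#' @return A `cell_table` tibble: `step`, `cell`, `lat`, `sightings`,
#'   `presence`, `effort_m2` and the covariate means / max `slope`.
#' @export
summarize_grid <- function(alloc, sightings, segments, env, weighted = TRUE) {
  grid <- attr(env, "grid")
  cov_names <- c("lat", "dshore_km", "sst", "front_z", "chla", "pp",
                 "depth", "slope", "vnorth", "waveheight")
  # covariates observed on the segments themselves win over the env lookup
  seg_cov <- intersect(cov_names, names(segments))
  env_cov <- setdiff(intersect(cov_names, names(env)), seg_cov)
  covars <- c(seg_cov, env_cov)
  seg <- dplyr::select(tibble::as_tibble(segments), "segment", "step",
                       "length_m", "effort_m2", dplyr::all_of(seg_cov))
  al <- dplyr::left_join(tibble::as_tibble(alloc), seg, by = "segment") |>
    dplyr::mutate(effort_alloc = .data$effort_m2 * .data$alloc_m / .data$length_m,
                  wt = if (weighted) .data$alloc_m else 1)

  if (length(env_cov)) {
    al <- dplyr::left_join(al, dplyr::select(tibble::as_tibble(env),
                                             "step", "cell",
                                             dplyr::all_of(env_cov)),
                           by = c("step", "cell"))
  }

  cellday <- al |>
    dplyr::summarise(
      effort_m2 = sum(.data$effort_alloc),
      track_m = sum(.data$alloc_m),
      dplyr::across(dplyr::all_of(setdiff(covars, "slope")),
                    ~ stats::weighted.mean(.x, w = wt)),
      dplyr::across(dplyr::any_of("slope"), max),
      .by = c("step", "cell"))

  sig <- tibble::as_tibble(sightings)
  if (nrow(sig) && !"cell" %in% names(sig)) {
    if (is.null(grid)) stop("need env grid attribute to locate sightings.",
                            call. = FALSE)
    sig$cell <- locate_cell(grid, sig$x_km, sig$y_km)
  }
  counts <- if (nrow(sig)) {
    dplyr::summarise(sig, sightings = dplyr::n(), .by = c("step", "cell"))
  } else {
    tibble::tibble(step = integer(0), cell = integer(0), sightings = integer(0))
  }

  orphan <- dplyr::anti_join(counts, cellday, by = c("step", "cell"))
  if (nrow(orphan)) {
    warning(sum(orphan$sightings),
            " sighting(s) in cell-days without effort were excluded.",
            call. = FALSE)
  }

  out <- dplyr::left_join(cellday, counts, by = c("step", "cell")) |>
    dplyr::mutate(sightings = dplyr::coalesce(.data$sightings, 0L),
                  presence = as.integer(.data$sightings >= 1)) |>
    dplyr::filter(.data$effort_m2 > 0) |>
    dplyr::arrange(.data$step, .data$cell)
  attr(out, "grid") <- grid
  class(out) <- c("cell_table", class(out))
  out
}
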