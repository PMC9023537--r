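#' Define a planar analysis grid
#'
#' The modeling grid is a regular block of square cells in a projected,
#' kilometre-scaled plane. The x axis runs cross-shelf (the coastline sits at
#' `x = coast_x_km`, depth increases offshore), the y axis runs south to
#' north. Latitude is assigned per row from `lat0` at the southern edge using
#' 111.195 km per degree, which is what links planar y to the latitudinal
#' centroid analysis.
#'
#' @param cell_km Cell edge length in kilometres (default 10, the resolution
#'   at which sightings, effort and covariates are summarized).
#' @param nx,ny Number of cells across-shelf (x) and along-shore (y).
#' @param lat0 Latitude (decimal degrees N) of the southern grid edge.
#' @param coast_x_km x coordinate of the coastline; distance from shore for a
#'   cell is its x centre minus this value.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(cell_km = 10, nx = 5, ny = 4, lat0 = 25)
#' grid_cells(g)
#' @export
grid_spec <- function(cell_km = 10, nx = 20, ny = 30, lat0 = 25,
                      coast_x_km = 0) {
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0) {
    stop("`cell_km` must be a single positive number.", call. = FALSE)
  }
  if (nx < 1 || ny < 1 || nx != round(nx) || ny != round(ny)) {
    stop("`nx` and `ny` must be positive integers.", call. = FALSE)
  }
  structure(
    list(cell_km = cell_km, nx = as.integer(nx), ny = as.integer(ny),
         lat0 = lat0, coast_x_km = coast_x_km,
         km_per_degree = 111.195),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.1f km (%.0f x %.0f km), lat %.2f-%.2f N\n",
              x$nx, x$ny, x$cell_km, x$nx * x$cell_km, x$ny * x$cell_km,
              x$lat0, x$lat0 + x$ny * x$cell_km / x$km_per_degree))
  invisible(x)
}

#' Enumerate grid cells
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `cell` (integer id, row-major from
#'   the south-west corner), `ix`, `iy` (column/row indices), `x_km`, `y_km`
#'   (cell centres), `lat` (centre latitude, degrees N) and `dshore_km`
#'   (centre distance from the coastline).
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  idx <- tidyr::expand_grid(iy = seq_len(grid$ny), ix = seq_len(grid$nx))
  dplyr::mutate(idx,
    cell = (.data$iy - 1L) * grid$nx + .data$ix,
    x_km = (.data$ix - 0.5) * grid$cell_km,
    y_km = (.data$iy - 0.5) * grid$cell_km,
    lat = grid$lat0 + .data$y_km / grid$km_per_degree,
    dshore_km = .data$x_km - grid$coast_x_km,
    .before = 1L
  ) |>
    dplyr::select("cell", "ix", "iy", "x_km", "y_km", "lat", "dshore_km") |>
    dplyr::arrange(.data$cell)
}

#' Locate points on the grid
#'
#' @param grid A [grid_spec()].
#' @param x_km,y_km Point coordinates in grid kilometres.
#' @return Integer cell ids; `NA` for points outside the grid extent.
#' @export
locate_cell <- function(grid, x_km, y_km) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- ceiling(x_km / grid$cell_km)
  iy <- ceiling(y_km / grid$cell_km)
  # points exactly on the lower/left edge belong to the first cell
  ix[x_km == 0] <- 1L
  iy[y_km == 0] <- 1L
  out <- (iy - 1L) * grid$nx + ix
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  out[bad] <- NA_integer_
  as.integer(out)
}
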