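#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a probability-of-occurrence surface
#'
#' @param object A `prediction_surface` or `ensemble_surface`.
#' @param steps Steps to facet over (default: all present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_surface
#' @export
autoplot.prediction_surface <- function(object, steps = NULL, ...) {
  d <- tibble::as_tibble(object)
  grid <- attr(object, "grid")
  if (!is.null(steps)) d <- d[d$step %in% steps, , drop = FALSE]
  if (!is.null(grid) && !all(c("x_km", "y_km") %in% names(d))) {
    d <- dplyr::left_join(d, grid_cells(grid)[, c("cell", "x_km", "y_km")],
                          by = "cell")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x_km, .data$y_km, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~step) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km, offshore →)", y = "y (km, north →)",
                  fill = "P(occurrence)")
}

#' Distance histogram with the fitted detection function
#'
#' @param object A `detection_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot of the scaled sighting-distance histogram and the
#'   fitted key `g(x)` (at mean covariates).
#' @method autoplot detection_fit
#' @export
autoplot.detection_fit <- function(object, bins = 20, ...) {
  x <- if (!is.null(object$events)) object$events$distance_m else
    object$data$distance_m
  sigma <- stats::median(fit_sigma(object, if (!is.null(object$events))
    object$events else object$data))
  xx <- seq(0, object$w, length.out = 200)
  curve <- tibble::tibble(
    distance_m = xx,
    g = detection_key(xx, object$key, sigma, object$shape))
  mu <- key_integral(object$key, sigma, object$shape, object$w)
  h <- graphics::hist(x, breaks = seq(0, object$w, length.out = bins + 1),
                      plot = FALSE)
  bars <- tibble::tibble(mid = h$mids, density = h$density * mu)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = bars, ggplot2::aes(.data$mid, .data$density),
                      width = object$w / bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$distance_m, .data$g),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "perpendicular distance (m)", y = "g(x)",
                  title = sprintf("%s key, w = %.0f m", object$key, object$w))
}

#' Centroid series with SARIMA forecast bands
#'
#' @param object A `centroid_series`.
#' @param forecast Optional tibble from [forecast_sarima()]; drawn after the
#'   series with 1 and 2 SE ribbons.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot centroid_series
#' @export
autoplot.centroid_series <- function(object, forecast = NULL, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$month, .data$centroid_lat)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "month", y = "weighted mean latitude (°N)")
  if (!is.null(forecast)) {
    f <- dplyr::mutate(forecast, month = max(d$month) + .data$h)
    p <- p +
      ggplot2::geom_ribbon(data = f,
                           ggplot2::aes(.data$month, ymin = .data$lo2,
                                        ymax = .data$hi2),
                           inherit.aes = FALSE, fill = "grey80") +
      ggplot2::geom_ribbon(data = f,
                           ggplot2::aes(.data$month, ymin = .data$lo1,
                                        ymax = .data$hi1),
                           inherit.aes = FALSE, fill = "grey65") +
      ggplot2::geom_line(data = f, ggplot2::aes(.data$month, .data$mean),
                         colour = "firebrick")
  }
  p
}

#' Partial smooth responses of a fitted distribution model
#'
#' Sweeps each covariate over its training range with the others held at
#' their training means and plots the centred partial linear predictor.
#'
#' @param object A converged `sdm_fit`.
#' @param n_grid Sweep resolution.
#' @param ... Unused.
#' @return A ggplot faceted by term.
#' @method autoplot sdm_fit
#' @export
autoplot.sdm_fit <- function(object, n_grid = 100, ...) {
  stopifnot(isTRUE(object$converged))
  sw <- purrr::map(object$terms, function(v) {
    partial_response(object, v, n_grid) |>
      dplyr::mutate(term = v)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(sw, ggplot2::aes(.data$value, .data$partial)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "covariate value", y = "partial effect (logit)")
}

#' Partial response sweep for one covariate
#'
#' @param fit A converged `sdm_fit`.
#' @param term Covariate name.
#' @param n_grid Sweep resolution.
#' @return A tibble `value`, `partial` (centred partial linear predictor).
#' @export
partial_response <- function(fit, term, n_grid = 100) {
  stopifnot(isTRUE(fit$converged), term %in% names(fit$ranges))
  base <- fit$gam$model
  nd <- tibble::as_tibble(purrr::map(fit$ranges, ~ mean(.x)))
  nd <- nd[rep(1, n_grid), , drop = FALSE]
  nd[[term]] <- seq(fit$ranges[[term]][1], fit$ranges[[term]][2],
                    length.out = n_grid)
  nd$effort_m2 <- fit$ref_effort
  eta <- as.numeric(stats::predict(fit$gam, newdata = nd, type = "link"))
  tibble::tibble(value = nd[[term]], partial = eta - mean(eta))
}
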