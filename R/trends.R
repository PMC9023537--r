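#' Probability-weighted latitudinal centroid of a prediction surface
#'
#' `sum(lat_c * p_c * area_c) / sum(p_c * area_c)` over unmasked cells. On
#' the planar synthetic grid all cells share one area, so the area weights
#' cancel; for geographic grids pass per-cell areas (e.g. cos-latitude
#' corrected).
#'
#' @param surface A `prediction_surface` (single step) or any tibble with
#'   `lat` and `p`.
#' @param area Optional per-cell areas aligned with the rows.
#' @return Weighted mean latitude (degrees N).
#' @export
latitudinal_centroid <- function(surface, area = NULL) {
  d <- tibble::as_tibble(surface)
  ok <- !is.na(d$p)
  w <- d$p[ok] * (if (is.null(area)) 1 else area[ok])
  if (!any(ok) || sum(w) <= 0) {
    stop("surface has no unmasked cell with positive probability.", call. = FALSE)
  }
  sum(d$lat[ok] * w) / sum(w)
}

#' Monthly centroid series from a stack of prediction surfaces
#'
#' @param surface A multi-step `prediction_surface`; one centroid per step.
#' @param label Model label stored with the series.
#' @return A `centroid_series` tibble: `month` (step index), `centroid_lat`,
#'   `model`.
#' @export
centroid_series <- function(surface, label = "sdm") {
  d <- tibble::as_tibble(surface)
  out <- d |>
    dplyr::group_by(month = .data$step) |>
    dplyr::group_modify(~ tibble::tibble(centroid_lat = latitudinal_centroid(.x))) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = label)
  if (any(diff(out$month) != 1)) {
    stop("centroid series has gaps in the month index.", call. = FALSE)
  }
  class(out) <- c("centroid_series", class(out))
  out
}

#' Fit a seasonal ARIMA model to a monthly series
#'
#' Maximum-likelihood SARIMA fit with the default order
#' `(1,1,1)(0,1,1)[12]` — first-order monthly and annual (seasonal)
#' differencing with one non-seasonal AR and MA term and one seasonal MA
#' term, the minimal specification exposing both a month-to-month
#' autoregressive coefficient (`ar1`) and a seasonal moving-average
#' coefficient (`sma1`). Coefficient t statistics use the large-sample
#' normal/t approximation with `n - d - D*period - k` degrees of freedom.
#'
#' @param x Numeric series (e.g. `centroid_lat` from [centroid_series()]) or
#'   a `centroid_series` tibble.
#' @param order Non-seasonal `(p, d, q)`.
#' @param seasonal Seasonal `(P, D, Q)`.
#' @param period Seasonal period (12 for monthly data).
#' @return An object of class `sarima_fit` wrapping `stats::arima`.
#' @export
fit_sarima <- function(x, order = c(1, 1, 1), seasonal = c(0, 1, 1),
                       period = 12) {
  if (inherits(x, "centroid_series")) x <- x$centroid_lat
  x <- as.numeric(x)
  if (length(x) < 3 * period) {
    stop("series too short: need at least 3 seasonal periods.", call. = FALSE)
  }
  fit <- try(stats::arima(stats::ts(x, frequency = period), order = order,
                          seasonal = list(order = seasonal, period = period),
                          method = "ML"), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # CSS-ML fallback for hard likelihood surfaces
    fit <- try(stats::arima(stats::ts(x, frequency = period), order = order,
                            seasonal = list(order = seasonal, period = period)),
               silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop("SARIMA fit did not converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  k <- length(stats::coef(fit))
  df <- length(x) - order[2] - seasonal[2] * period - k
  est <- stats::coef(fit)
  se <- sqrt(pmax(diag(fit$var.coef), 0))
  structure(list(
    arima = fit, order = order, seasonal = seasonal, period = period,
    n = length(x), df = df,
    coefficients = tibble::tibble(
      term = names(est), estimate = unname(est), std.error = unname(se),
      statistic = unname(est / se),
      p.value = 2 * stats::pt(-abs(unname(est / se)), df = df))
  ), class = "sarima_fit")
}

#' @export
print.sarima_fit <- function(x, ...) {
  cat(sprintf("<sarima_fit> (%s)(%s)[%d], n=%d, AIC=%.1f\n",
              paste(x$order, collapse = ","),
              paste(x$seasonal, collapse = ","), x$period, x$n,
              stats::AIC(x$arima)))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy sarima_fit
#' @export
tidy.sarima_fit <- function(x, ...) x$coefficients

#' @method glance sarima_fit
#' @export
glance.sarima_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, sigma2 = x$arima$sigma2,
                 logLik = as.numeric(stats::logLik(x$arima)),
                 AIC = stats::AIC(x$arima))
}

#' Forecast a fitted SARIMA model with 1 and 2 SE bands
#'
#' @param fit A `sarima_fit`.
#' @param horizon Months ahead (default 60, i.e. five years).
#' @return A tibble: `h`, `mean`, `se`, `lo1`, `hi1`, `lo2`, `hi2` (mean
#'   plus/minus 1 and 2 forecast standard errors).
#' @export
forecast_sarima <- function(fit, horizon = 60) {
  stopifnot(inherits(fit, "sarima_fit"))
  if (horizon <= 0) stop("`horizon` must be positive.", call. = FALSE)
  pr <- stats::predict(fit$arima, n.ahead = horizon)
  m <- as.numeric(pr$pred); s <- as.numeric(pr$se)
  tibble::tibble(h = seq_len(horizon), mean = m, se = s,
                 lo1 = m - s, hi1 = m + s, lo2 = m - 2 * s, hi2 = m + 2 * s)
}
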