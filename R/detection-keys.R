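#' Line-transect detection key functions
#'
#' Shape component of the detection process: `g(x)` is the probability of
#' detecting an animal at perpendicular distance `x` relative to detection on
#' the trackline, so `g(0) = 1`. Two standard keys are provided:
#' half-normal `g(x) = exp(-x^2 / (2 sigma^2))` and hazard-rate
#' `g(x) = 1 - exp(-(x/sigma)^(-shape))` with `shape > 0`.
#'
#' @param x Perpendicular distance(s), metres, >= 0.
#' @param key `"hn"` (half-normal) or `"hr"` (hazard-rate).
#' @param sigma Scale parameter, metres, > 0. May be a vector matched to `x`
#'   when the scale carries covariates.
#' @param shape Hazard-rate shape (ignored for half-normal).
#' @return `g(x)` in (0, 1].
#' @export
detection_key <- function(x, key = c("hn", "hr"), sigma, shape = NULL) {
  key <- match.arg(key)
  if (any(sigma <= 0)) stop("`sigma` must be positive.", call. = FALSE)
  if (key == "hn") {
    exp(-x^2 / (2 * sigma^2))
  } else {
    if (is.null(shape) || any(shape <= 0)) {
      stop("hazard-rate key needs a positive `shape`.", call. = FALSE)
    }
    ifelse(x == 0, 1, 1 - exp(-(x / sigma)^(-shape)))
  }
}

# integral of the key over [0, w]; analytic for half-normal, adaptive
# quadrature for hazard-rate (scalar sigma)
key_integral <- function(key, sigma, shape = NULL, w) {
  if (key == "hn") {
    sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5)
  } else {
    stats::integrate(function(x) detection_key(x, "hr", sigma, shape),
                     0, w, rel.tol = 1e-10)$value
  }
}

# vectorized over sigma (covariate-specific scales share shape)
key_integral_v <- function(key, sigma, shape = NULL, w) {
  if (key == "hn") {
    key_integral("hn", sigma, w = w)
  } else {
    vapply(sigma, function(s) key_integral("hr", s, shape, w), numeric(1))
  }
}
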