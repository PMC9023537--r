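#' Select the best detection model by AIC
#'
#' @param fits A list of `detection_fit` objects (unconverged entries are
#'   dropped). Ties on AIC (within `tol`) go to the model with fewest
#'   parameters.
#' @param tol Absolute AIC difference treated as a tie.
#' @return The winning `detection_fit`, with the full comparison table
#'   attached as attribute `aic_table`.
#' @export
select_by_aic <- function(fits, tol = 1e-8) {
  fits <- Filter(function(f) inherits(f, "detection_fit") && isTRUE(f$converged),
                 fits)
  if (!length(fits)) stop("no converged candidate fits.", call. = FALSE)
  tab <- purrr::map(fits, glance) |>
    purrr::list_rbind() |>
    dplyr::mutate(model = seq_along(fits), .before = 1L)
  best_aic <- min(tab$AIC)
  tied <- which(tab$AIC <= best_aic + tol)
  pick <- tied[which.min(tab$npar[tied])]
  out <- fits[[pick]]
  attr(out, "aic_table") <- dplyr::arrange(tab, .data$AIC, .data$npar)
  out
}

#' Average detection probability within the truncated strip
#'
#' Computes `p-bar = p(0) * (1/w) * integral_0^w g(x) dx`, averaged over the
#' empirical covariate distribution (by default the covariate values observed
#' at the sightings the model was fit to). For a single-platform MCDS fit
#' `p(0) = 1`; for an MRDS fit `p(0)` is the combined trackline probability
#' from the mark-recapture component. The CV is obtained by a nonparametric
#' bootstrap over sightings/events (resample rows, refit, recompute).
#'
#' @param fit A `detection_fit`.
#' @param newdata Optional covariate rows over which to average (defaults to
#'   the fitting data; pass effort segments to average over effort instead).
#' @param B Bootstrap replicates for the CV (default 999); `B = 0` skips the
#'   CV.
#' @param seed Seed for the bootstrap resampling.
#' @return A list: `p` (average detection probability), `cv`, `se`, `boot`
#'   (replicate values).
#' @export
average_detection_probability <- function(fit, newdata = NULL, B = 999,
                                          seed = 1L) {
  stopifnot(inherits(fit, "detection_fit"))
  pbar <- function(f, nd) {
    sigma <- fit_sigma(f, nd)
    shape <- f$shape
    mu <- key_integral_v(f$key, sigma, shape, f$w)
    p0 <- if (is.null(f$mr)) rep(1, nrow(nd)) else mr_p0(f, nd)
    mean(p0 * mu / f$w)
  }
  nd <- if (is.null(newdata)) {
    if (!is.null(fit$events)) fit$events else fit$data
  } else tibble::as_tibble(newdata)
  p_hat <- pbar(fit, nd)

  boot <- NULL
  cv <- se <- NA_real_
  if (B > 0) {
    src <- if (!is.null(fit$events)) fit$events else fit$data
    boot <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(B), function(b) {
        res <- src[sample.int(nrow(src), replace = TRUE), , drop = FALSE]
        f_b <- try(suppressWarnings(
          if (fit$type == "mrds") {
            fit_mrds(res, key = fit$key, w = fit$w,
                     scale_formula = fit$scale_formula,
                     mr_formula = fit$mr$formula, n_min = 1)
          } else {
            fit_mcds(res, key = fit$key, w = fit$w,
                     scale_formula = fit$scale_formula, n_min = 1)
          }), silent = TRUE)
        if (inherits(f_b, "try-error")) return(NA_real_)
        nb <- if (is.null(newdata)) {
          if (!is.null(f_b$events)) f_b$events else f_b$data
        } else nd
        try_p <- try(pbar(f_b, nb), silent = TRUE)
        if (inherits(try_p, "try-error")) NA_real_ else try_p
      }, numeric(1))
    })
    ok <- boot[is.finite(boot)]
    if (length(ok) > 1) {
      se <- stats::sd(ok)
      cv <- se / p_hat
    }
  }
  list(p = p_hat, cv = cv, se = se, boot = boot)
}

#' Effective search effort (swept area)
#'
#' Effort for a trackline segment is the product of its length, the average
#' detection probability within the strip, and the truncation distance,
#' optionally doubled when both sides of the aircraft are counted.
#'
#' @param length_m Trackline length(s), m.
#' @param p Average detection probability in `[0, 1]`.
#' @param w_m Truncation distance, m.
#' @param sides 1 (literal length x p x w, the default) or 2.
#' @return Effective area(s) in m^2.
#' @examples
#' effective_effort(10000, 0.394, 300)  # 1,182,000 m^2
#' @export
effective_effort <- function(length_m, p, w_m, sides = 1) {
  if (any(length_m < 0) || any(p < 0) || any(w_m < 0)) {
    stop("effort inputs must be nonnegative.", call. = FALSE)
  }
  length_m * p * w_m * sides
}

#' Transfer a fitted detection function to distance-less effort
#'
#' Applies a detection function fitted on one survey to effort segments from
#' a survey that recorded no sighting distances, evaluating the per-segment
#' average detection probability at each segment's covariates and converting
#' to effective searched area.
#'
#' @param fit A `detection_fit`.
#' @param segments Effort tibble with `length_m` and every covariate the fit
#'   requires (an unseen factor level is an error naming the level).
#' @param sides Passed to [effective_effort()].
#' @return `segments` with columns `p_detect` and `effort_m2` appended.
#' @export
transfer_detection <- function(fit, segments, sides = 1) {
  stopifnot(inherits(fit, "detection_fit"))
  seg <- tibble::as_tibble(segments)
  sigma <- fit_sigma(fit, seg)
  mu <- key_integral_v(fit$key, sigma, fit$shape, fit$w)
  p0 <- if (is.null(fit$mr)) 1 else mr_p0(fit, seg)
  seg$p_detect <- p0 * mu / fit$w
  seg$effort_m2 <- effective_effort(seg$length_m, seg$p_detect, fit$w, sides)
  seg
}
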