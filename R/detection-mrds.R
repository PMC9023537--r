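#' Fit a dual-observer mark-recapture detection function (point independence)
#'
#' Joint fit of (a) a pooled distance-shape component — the MCDS conditional
#' likelihood of perpendicular distances over all unique events detected by
#' either team — and (b) a conditional-detection logistic regression
#' estimating detection probability on the trackline, `p(0)`. Under point
#' independence the teams are assumed to detect independently only at zero
#' perpendicular distance, so the overall detection function is
#' `p(x) = p.(0 | covariates) * g(x)`, with
#' `p.(0) = 1 - (1 - p_1(0)) (1 - p_2(0))` the probability that at least one
#' team detects an animal on the trackline.
#'
#' The conditional component stacks, for every event detected by one team,
#' a Bernoulli trial for whether the *other* team also detected it, and fits
#' `mr_formula` by `glm(..., family = binomial)`. The total log-likelihood is
#' the sum of the two components and AIC counts both parameter sets.
#'
#' @param events One row per unique sighting event (e.g. from
#'   [match_duplicates()]): `distance_m`, logical `observer_1` /
#'   `observer_2` detection indicators, and any covariates.
#' @param key,w,scale_formula,n_min As in [fit_mcds()].
#' @param mr_formula RHS-only formula for the conditional-detection logistic
#'   in terms of `distance_m`, `observer` (factor `"1"`/`"2"`) and
#'   covariates; use `~ distance_m * observer` for the distance-by-observer
#'   interaction.
#' @return A `detection_fit` whose `mr` element holds the fitted `glm`,
#'   per-team `p0_team` and `p0_combined`.
#' @export
fit_mrds <- function(events, key = c("hn", "hr"), w,
                     scale_formula = ~1, mr_formula = ~ distance_m + observer,
                     n_min = 20) {
  key <- match.arg(key)
  ev <- tibble::as_tibble(events)
  stopifnot(all(c("distance_m", "observer_1", "observer_2") %in% names(ev)))
  ev <- ev[ev$distance_m <= w & ev$distance_m >= 0, , drop = FALSE]
  n_dup <- sum(ev$observer_1 & ev$observer_2)
  if (n_dup == 0) {
    stop("no duplicate detections; the mark-recapture component is unidentifiable.",
         call. = FALSE)
  }

  ds <- fit_mcds(ev, key = key, w = w, scale_formula = scale_formula,
                 n_min = n_min)

  # conditional trials: response = "did observer k detect", restricted to
  # events the other observer detected
  mk <- function(obs) {
    other <- if (obs == "1") "observer_2" else "observer_1"
    self <- if (obs == "1") "observer_1" else "observer_2"
    sub <- ev[ev[[other]], , drop = FALSE]
    sub$detected <- sub[[self]]
    sub$observer <- factor(obs, levels = c("1", "2"))
    sub
  }
  stack <- dplyr::bind_rows(mk("1"), mk("2"))
  mrf <- stats::update(mr_formula, detected ~ .)
  gl <- stats::glm(mrf, family = stats::binomial(), data = stack)

  nd0 <- stack[!duplicated(stack$observer), , drop = FALSE]
  nd0 <- nd0[order(nd0$observer), , drop = FALSE]
  nd0$distance_m <- 0
  p0_team <- stats::setNames(
    as.numeric(stats::predict(gl, newdata = nd0, type = "response")),
    paste0("observer_", nd0$observer))

  fit <- ds
  fit$type <- "mrds"
  fit$mr <- list(glm = gl, formula = mr_formula, stack = stack,
                 p0_team = p0_team,
                 p0_combined = 1 - prod(1 - p0_team),
                 loglik = as.numeric(stats::logLik(gl)),
                 npar = length(stats::coef(gl)))
  fit$loglik <- ds$loglik + fit$mr$loglik
  fit$npar <- ds$npar + fit$mr$npar
  fit$AIC <- -2 * fit$loglik + 2 * fit$npar
  fit$events <- ev
  fit
}

# combined trackline probability for covariate rows (distance forced to 0)
mr_p0 <- function(fit, newdata) {
  if (is.null(fit$mr)) return(rep(1, nrow(newdata)))
  p <- sapply(c("1", "2"), function(obs) {
    nd <- newdata
    nd$distance_m <- 0
    nd$observer <- factor(obs, levels = c("1", "2"))
    as.numeric(stats::predict(fit$mr$glm, newdata = nd, type = "response"))
  })
  p <- matrix(p, nrow = nrow(newdata))
  1 - (1 - p[, 1]) * (1 - p[, 2])
}
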