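#' Fit a single-platform (MCDS) detection function
#'
#' Maximizes the standard conditional likelihood of perpendicular sighting
#' distances for a line transect with `g(0) = 1`:
#' `f(x_i) = g(x_i; sigma_i) / integral_0^w g(u; sigma_i) du`, where the key
#' scale carries covariates on the log scale, `sigma_i = exp(X_i beta)`.
#' Interval-recorded distances (e.g. wing-strut bins) are handled by an
#' interval-censored likelihood using `P(lo < x <= hi)`, or by their
#' midpoints when `intervals = "midpoint"`.
#'
#' @param data Tibble of sightings with a `distance_m` column (or `dist_lo_m`
#'   / `dist_hi_m` for binned data) and any covariates named in
#'   `scale_formula`.
#' @param key `"hn"` (half-normal) or `"hr"` (hazard-rate,
#'   `g(x) = 1 - exp(-(x/sigma)^(-shape))`).
#' @param w Right truncation distance (m); all distances must lie in
#'   `[0, w]`.
#' @param scale_formula RHS-only formula for covariates on `log(sigma)`
#'   (default `~ 1`).
#' @param n_min Minimum number of sightings required to attempt a fit.
#' @param intervals `"censored"` (default, exact likelihood for binned rows)
#'   or `"midpoint"`.
#' @return A `detection_fit` with elements `par`, `beta`, `shape`, `loglik`,
#'   `npar`, `AIC`, `vcov`, `converged`, plus the inputs needed to predict.
#' @export
fit_mcds <- function(data, key = c("hn", "hr"), w, scale_formula = ~1,
                     n_min = 20, intervals = c("censored", "midpoint")) {
  key <- match.arg(key)
  intervals <- match.arg(intervals)
  d <- tibble::as_tibble(data)
  binned <- all(c("dist_lo_m", "dist_hi_m") %in% names(d)) &&
    !"distance_m" %in% names(d)
  if (binned && intervals == "midpoint") {
    d$distance_m <- (d$dist_lo_m + d$dist_hi_m) / 2
    binned <- FALSE
  }
  n <- nrow(d)
  if (n < n_min) {
    stop(sprintf("only %d sightings; %d required to fit.", n, n_min),
         call. = FALSE)
  }
  x <- if (binned) d$dist_hi_m else d$distance_m
  if (any(x < 0 | x > w)) stop("distances outside [0, w].", call. = FALSE)
  if (!binned && stats::sd(d$distance_m) == 0) {
    stop("degenerate distances (no spread); detection scale is not identifiable.",
         call. = FALSE)
  }

  tf <- stats::terms(scale_formula)
  X <- stats::model.matrix(tf, stats::model.frame(tf, d))
  xlevels <- stats::.getXlevels(tf, stats::model.frame(tf, d))
  p_beta <- ncol(X)

  nll <- function(par) {
    beta <- par[seq_len(p_beta)]
    sigma <- exp(drop(X %*% beta))
    shape <- if (key == "hr") exp(par[p_beta + 1L]) else NULL
    if (any(!is.finite(sigma)) || any(sigma > 1e7) || any(sigma < 1e-7)) {
      return(1e10)
    }
    us <- unique(sigma)
    mu <- key_integral_v(key, us, shape, w)[match(sigma, us)]
    if (binned) {
      num <- vapply(seq_len(n), function(i) {
        lo <- d$dist_lo_m[i]; hi <- d$dist_hi_m[i]
        if (key == "hn") {
          key_integral("hn", sigma[i], w = hi) - key_integral("hn", sigma[i], w = lo)
        } else {
          stats::integrate(function(z) detection_key(z, "hr", sigma[i], shape),
                           lo, hi, rel.tol = 1e-9)$value
        }
      }, numeric(1))
      ll <- sum(log(pmax(num, 1e-300))) - sum(log(mu))
    } else {
      g <- detection_key(d$distance_m, key, sigma, shape)
      ll <- sum(log(pmax(g, 1e-300))) - sum(log(mu))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  x0 <- if (binned) (d$dist_lo_m + d$dist_hi_m) / 2 else d$distance_m
  start_sigma <- log(max(stats::sd(x0), w / 20))
  starts <- list(c(start_sigma, rep(0, p_beta - 1L)),
                 c(start_sigma + 0.7, rep(0, p_beta - 1L)),
                 c(start_sigma - 0.7, rep(0, p_beta - 1L)))
  if (key == "hr") starts <- lapply(starts, function(s) c(s, log(2)))

  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
  }
  if (is.null(best) || best$value >= 1e9) {
    stop("detection function did not converge; optimizer value ",
         if (is.null(best)) "unavailable" else format(best$value), call. = FALSE)
  }

  hess <- try(stats::optimHess(best$par, nll), silent = TRUE)
  vc <- if (!inherits(hess, "try-error")) try(solve(hess), silent = TRUE) else NULL
  if (inherits(vc, "try-error")) vc <- NULL

  npar <- length(best$par)
  fit <- structure(list(
    type = "mcds", key = key, w = w,
    scale_formula = scale_formula, xlevels = xlevels,
    par = best$par,
    beta = stats::setNames(best$par[seq_len(p_beta)], colnames(X)),
    shape = if (key == "hr") exp(best$par[p_beta + 1L]) else NULL,
    loglik = -best$value, npar = npar, AIC = 2 * best$value + 2 * npar,
    vcov = vc, converged = best$convergence == 0,
    n = n, data = d, mr = NULL
  ), class = "detection_fit")
  fit
}

# per-row key scale from a fit's covariate model
fit_sigma <- function(fit, newdata) {
  tf <- stats::delete.response(stats::terms(fit$scale_formula))
  for (v in names(fit$xlevels)) {
    seen <- fit$xlevels[[v]]
    got <- unique(as.character(newdata[[v]]))
    unseen <- setdiff(got, seen)
    if (length(unseen)) {
      stop("covariate '", v, "' has level(s) unseen at fitting: ",
           paste(unseen, collapse = ", "), call. = FALSE)
    }
    newdata[[v]] <- factor(newdata[[v]], levels = seen)
  }
  X <- stats::model.matrix(tf, stats::model.frame(tf, newdata,
                                                  na.action = stats::na.fail))
  unname(exp(drop(X %*% fit$beta)))
}

#' Evaluate a fitted detection function
#'
#' @param object A `detection_fit`.
#' @param distance_m Distances (m) at which to evaluate the key `g(x)`.
#' @param newdata Optional covariate rows (recycled against `distance_m`).
#' @param ... Unused.
#' @return `g(distance)` given the fitted (covariate-specific) scale.
#' @export
predict.detection_fit <- function(object, distance_m, newdata = NULL, ...) {
  sigma <- if (is.null(newdata)) {
    fit_sigma(object, object$data)[1]
  } else {
    fit_sigma(object, newdata)
  }
  detection_key(distance_m, object$key, sigma, object$shape)
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit %s> key=%s w=%.0f m, n=%d, logLik=%.2f, AIC=%.2f\n",
              x$type, x$key, x$w, x$n, x$loglik, x$AIC))
  if (!is.null(x$mr)) {
    cat(sprintf("  MR trackline p(0): %s (combined %.3f)\n",
                paste(sprintf("%s=%.3f", names(x$mr$p0_team), x$mr$p0_team),
                      collapse = ", "), x$mr$p0_combined))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy detection_fit
#' @export
tidy.detection_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c(paste0("log_sigma:", names(x$beta)),
             if (x$key == "hr") "log_shape"),
    estimate = unname(x$par),
    std.error = if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else NA_real_
  )
  if (!is.null(x$mr)) {
    mr <- summary(x$mr$glm)$coefficients
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("mr:", rownames(mr)),
      estimate = mr[, 1], std.error = mr[, 2]))
  }
  out
}

#' @method glance detection_fit
#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(key = x$key, w = x$w, n = x$n, npar = x$npar,
                 logLik = x$loglik, AIC = x$AIC,
                 p0 = if (is.null(x$mr)) 1 else x$mr$p0_combined)
}
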