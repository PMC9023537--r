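test_that("half-normal MCDS recovers the scale and matches the quadrature oracle", {
  x <- sample_detected_distances(5000, "hn", sigma = 150, w = 300, seed = 9)
  fit <- fit_mcds(tibble::tibble(distance_m = x), key = "hn", w = 300)
  sigma_hat <- exp(fit$beta[[1]])
  expect_lt(abs(sigma_hat - 150) / 150, 0.05)

  # analytic p-bar equals adaptive quadrature of the fitted key to < 1e-6
  ap <- average_detection_probability(fit, B = 0)
  quad <- stats::integrate(function(z) detection_key(z, "hn", sigma_hat),
                           0, 300, rel.tol = 1e-10)$value / 300
  expect_lt(abs(ap$p - quad), 1e-6)
  # and the closed-form erf expression agrees with both
  expect_lt(abs(ap$p - hn_pbar(sigma_hat, 300)), 1e-9)

  expect_error(fit_mcds(tibble::tibble(distance_m = rep(0, 100)),
                        key = "hn", w = 300), "degenerate")
  expect_error(fit_mcds(tibble::tibble(distance_m = x[1:5]), key = "hn",
                        w = 300), "required")
})

test_that("the key is a proper shape: g(0)=1, half-normal non-increasing", {
  expect_equal(detection_key(0, "hn", 150), 1)
  expect_equal(detection_key(0, "hr", 150, 2.5), 1)
  xs <- seq(0, 300, 5)
  g <- detection_key(xs, "hn", 150)
  expect_true(all(diff(g) <= 0))
  expect_true(all(g > 0 & g <= 1))
})

test_that("AIC model choice separates hazard-rate data from half-normal", {
  # strong-shoulder truth: shape 4 keeps g flat near the trackline
  wins <- vapply(1:20, function(s) {
    x <- sample_detected_distances(800, "hr", sigma = 130, shape = 4,
                                   w = 300, seed = 100 + s)
    d <- tibble::tibble(distance_m = x)
    f_hr <- fit_mcds(d, "hr", w = 300)
    f_hn <- fit_mcds(d, "hn", w = 300)
    f_hr$AIC < f_hn$AIC
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("AIC selection picks the lowest AIC with a fewest-parameter tie-break", {
  f1 <- structure(list(key = "hn", w = 300, n = 10, npar = 3, loglik = -47,
                       AIC = 100.0, converged = TRUE, mr = NULL),
                  class = "detection_fit")
  f2 <- structure(list(key = "hn", w = 300, n = 10, npar = 2, loglik = -48.6,
                       AIC = 101.2, converged = TRUE, mr = NULL),
                  class = "detection_fit")
  expect_identical(select_by_aic(list(f1, f2))$npar, 3)
  f3 <- structure(list(key = "hn", w = 300, n = 10, npar = 2, loglik = -48,
                       AIC = 100.0, converged = TRUE, mr = NULL),
                  class = "detection_fit")
  expect_identical(select_by_aic(list(f1, f3))$npar, 2)   # tie -> fewer params
  expect_identical(select_by_aic(list(f1))$AIC, 100.0)
  f_bad <- structure(list(converged = FALSE), class = "detection_fit")
  expect_error(select_by_aic(list(f_bad)), "converged")
})

test_that("MRDS point independence recovers the trackline probability", {
  ev <- simulate_mrds_events(12000, p0 = c(0.8, 0.7), sigma = 150, w = 300,
                             seed = 31)
  fit <- fit_mrds(ev, key = "hn", w = 300)
  expect_lt(abs(fit$mr$p0_team[["observer_1"]] - 0.8), 0.05)
  # the logistic-linear conditional extrapolates to x = 0, so the weaker
  # team's p(0) carries more functional-form bias; bound it more loosely
  expect_lt(abs(fit$mr$p0_team[["observer_2"]] - 0.7), 0.1)

  # all-duplicate data: p(0) = 1 and p-bar equals the MCDS p-bar
  ev2 <- dplyr::mutate(ev, observer_1 = TRUE, observer_2 = TRUE)
  # all-ones conditional response legitimately warns (p(0) at the boundary)
  fit2 <- suppressWarnings(fit_mrds(ev2, key = "hn", w = 300))
  expect_gt(fit2$mr$p0_combined, 0.999)
  mcds <- fit_mcds(ev2, key = "hn", w = 300)
  p_mr <- average_detection_probability(fit2, B = 0)$p
  p_ds <- average_detection_probability(mcds, B = 0)$p
  expect_equal(p_mr, p_ds, tolerance = 1e-3)

  no_dup <- dplyr::mutate(ev, observer_2 = FALSE)
  expect_error(fit_mrds(no_dup, key = "hn", w = 300), "duplicate")
})

test_that("glare-free data prefer the covariate-free detection model", {
  # a useless covariate is rejected when 2*dLL < 2, i.e. P(chisq_1 < 2) ~ 0.84
  wins <- vapply(1:100, function(s) {
    x <- sample_detected_distances(300, "hn", sigma = 150, w = 300,
                                   seed = 300 + s)
    d <- tibble::tibble(distance_m = x,
                        glare = withr::with_seed(400 + s,
                                                 stats::runif(300)))
    f0 <- fit_mcds(d, "hn", w = 300)
    f1 <- fit_mcds(d, "hn", w = 300, scale_formula = ~glare)
    f0$AIC < f1$AIC
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("average detection probability behaves as a scaled strip mean", {
  # p(0) = 1, g == 1 -> p-bar = 1: evaluate the formula at a flat key
  flat <- structure(list(type = "mcds", key = "hn", w = 300,
                         scale_formula = ~1, xlevels = list(),
                         beta = c("(Intercept)" = log(1e9)), shape = NULL,
                         data = tibble::tibble(distance_m = 1), mr = NULL,
                         converged = TRUE),
                    class = "detection_fit")
  expect_equal(average_detection_probability(flat, B = 0)$p, 1,
               tolerance = 1e-9)

  # bootstrap CV is reproducible and positive on real variation
  x2 <- sample_detected_distances(150, "hn", sigma = 150, w = 300, seed = 3)
  f2 <- fit_mcds(tibble::tibble(distance_m = x2), "hn", w = 300)
  a <- average_detection_probability(f2, B = 30, seed = 5)
  b <- average_detection_probability(f2, B = 30, seed = 5)
  expect_identical(a$boot, b$boot)
  expect_gt(a$cv, 0)
})

test_that("interval-censored fitting with midpoint mode equals exact midpoints", {
  x <- sample_detected_distances(800, "hn", sigma = 120, w = 300, seed = 13)
  breaks <- c(0, 50, 100, 180, 300)
  lo <- breaks[findInterval(x, breaks, rightmost.closed = TRUE)]
  hi <- breaks[findInterval(x, breaks, rightmost.closed = TRUE) + 1L]
  binned <- tibble::tibble(dist_lo_m = lo, dist_hi_m = hi)
  f_mid <- fit_mcds(binned, "hn", w = 300, intervals = "midpoint")
  f_exact <- fit_mcds(tibble::tibble(distance_m = (lo + hi) / 2), "hn", w = 300)
  expect_equal(f_mid$beta, f_exact$beta, tolerance = 1e-6)
  # censored likelihood also lands near the truth
  f_cens <- fit_mcds(binned, "hn", w = 300)
  expect_lt(abs(exp(f_cens$beta[[1]]) - 120) / 120, 0.1)
})

test_that("effective effort is the length x p x w product", {
  expect_equal(effective_effort(10000, 0.394, 300), 1182000)
  expect_equal(effective_effort(1000, 1, 300), 3e5)
  expect_equal(effective_effort(0, 0.5, 300), 0)
  expect_equal(effective_effort(1000, 0.5, 300, sides = 2), 3e5)
  expect_error(effective_effort(-1, 0.5, 300), "nonnegative")
})

test_that("detection transfer reproduces source effort and responds to covariates", {
  x <- sample_detected_distances(2000, "hn", sigma = 150, w = 300, seed = 17)
  sea <- withr::with_seed(18, sample(0:3, 2000, TRUE))
  d <- tibble::tibble(distance_m = x, beaufort = sea)
  fit <- fit_mcds(d, "hn", w = 300, scale_formula = ~beaufort)

  # identical covariates -> identical p
  seg <- tibble::tibble(length_m = 1000, beaufort = 2)
  tr <- transfer_detection(fit, seg)
  sig <- exp(fit$beta[["(Intercept)"]] + 2 * fit$beta[["beaufort"]])
  expect_equal(tr$p_detect, hn_pbar(sig, 300), tolerance = 1e-9)

  # worse sea state with a negative coefficient lowers p strictly
  if (fit$beta[["beaufort"]] < 0) {
    tr2 <- transfer_detection(fit, dplyr::mutate(seg, beaufort = 3))
    expect_lt(tr2$p_detect, tr$p_detect)
  }

  # whole-survey transfer onto a clone reproduces total effective effort
  clone <- tibble::tibble(length_m = rep(1000, 2000), beaufort = sea)
  tr3 <- transfer_detection(fit, clone)
  source_total <- sum(effective_effort(
    1000, average_detection_probability(fit, B = 0)$p, 300)) * 2000
  expect_lt(abs(sum(tr3$effort_m2) - source_total) / source_total, 0.02)

  # unseen factor level errors informatively
  dfac <- tibble::tibble(distance_m = x, sea = factor(sea))
  ffac <- fit_mcds(dfac, "hn", w = 300, scale_formula = ~sea)
  expect_error(
    transfer_detection(ffac, tibble::tibble(length_m = 1, sea = factor(7))),
    "unseen")
})
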