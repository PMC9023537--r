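test_that("collinearity screen flags high-rho pairs and the chla/pp pair", {
  d <- withr::with_seed(1, tibble::tibble(
    a = rnorm(1e4), b = rnorm(1e4), chla = rnorm(1e4), pp = rnorm(1e4)))
  d$dup <- d$a
  scr <- screen_collinearity(d, c("a", "b", "dup", "chla", "pp"))
  pick <- function(v1, v2) {
    scr$forbidden[(scr$var1 == v1 & scr$var2 == v2) |
                    (scr$var1 == v2 & scr$var2 == v1)]
  }
  expect_true(pick("a", "dup"))             # rho = 1
  expect_false(pick("a", "b"))              # independent noise
  expect_true(pick("chla", "pp"))           # always exclusive
  expect_lt(abs(scr$rho[scr$var1 == "a" & scr$var2 == "b"]), 0.05)

  # the threshold is strict: a pair at exactly rho_max is allowed
  zx <- as.numeric(scale(1:40))
  resid <- as.numeric(scale(stats::resid(lm(rnorm(40) ~ zx))))
  y <- 0.7 * zx + sqrt(1 - 0.49) * resid
  d2 <- tibble::tibble(x = zx, y = y)
  rho_obs <- stats::cor(zx, y)
  expect_equal(rho_obs, 0.7, tolerance = 1e-12)
  scr_at <- screen_collinearity(d2, c("x", "y"), rho_max = rho_obs)
  expect_false(scr_at$forbidden)
  scr_below <- screen_collinearity(d2, c("x", "y"), rho_max = rho_obs - 1e-9)
  expect_true(scr_below$forbidden)

  expect_warning(screen_collinearity(dplyr::mutate(d, k = 1),
                                     c("a", "k")), "constant")
})

test_that("candidate enumeration respects forbidden pairs and term hierarchy", {
  none <- tibble::tibble(var1 = character(0), var2 = character(0),
                         rho = numeric(0), forbidden = logical(0))
  cands <- enumerate_candidates(c("A", "B"), none, interaction = NULL)
  expect_length(cands, 4)                   # {}, A, B, A+B
  expect_true(any(purrr::map_lgl(cands, ~ length(.x$terms) == 0)))

  fb <- tibble::tibble(var1 = "A", var2 = "B", rho = 0.9, forbidden = TRUE)
  cands2 <- enumerate_candidates(c("A", "B"), fb, interaction = NULL)
  expect_length(cands2, 3)

  cands3 <- enumerate_candidates(c("front_z", "sst"), none)
  labels <- purrr::map_chr(cands3, ~ paste(sort(.x$terms), collapse = "+",
                                           sep = "") |>
                             paste(.x$interaction, sep = "|"))
  expect_true("front_z+sst|TRUE" %in% labels)     # interaction with mains
  expect_false(any(grepl("^\\|TRUE$", labels)))   # never without mains
  expect_false("front_z|TRUE" %in% labels)
})

test_that("the effort offset works as a contract and the null model explains 0", {
  set.seed(42)
  n <- 2000
  d <- tibble::tibble(
    presence = rbinom(n, 1, 0.3), effort_m2 = exp(rnorm(n, 13, 0.5)),
    sst = rnorm(n, 22, 3))

  f0 <- fit_sdm(d, character(0))
  expect_identical(f0$dev_expl, 0)          # deviance explained exactly 0

  # intercept-only at constant effort E: intercept = logit(0.3) - log(E)
  dE <- dplyr::mutate(d, effort_m2 = 2e5)
  fE <- fit_sdm(dE, character(0))
  p_hat <- mean(dE$presence)
  expect_equal(unname(coef(fE$gam)[1]), qlogis(p_hat) - log(2e5),
               tolerance = 1e-6)

  # doubling efforts shifts the linear predictor by -log 2 (the intercept
  # compensates), so predictions at each model's own matched offset agree
  f1 <- fit_sdm(d, "sst")
  d2 <- dplyr::mutate(d, effort_m2 = 2 * effort_m2)
  f2 <- fit_sdm(d2, "sst")
  expect_equal(unname(coef(f2$gam)[1]), unname(coef(f1$gam)[1]) - log(2),
               tolerance = 1e-6)
  nd1 <- tibble::tibble(sst = seq(16, 28, 1), effort_m2 = 1e5)
  nd2 <- dplyr::mutate(nd1, effort_m2 = 2e5)
  p1 <- predict(f1$gam, newdata = nd1, type = "link")
  p2 <- predict(f2$gam, newdata = nd2, type = "link")
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-6)
})

test_that("AIC is monotone under nesting up to the parameter penalty", {
  set.seed(7)
  d <- tibble::tibble(presence = rbinom(500, 1, 0.4),
                      effort_m2 = 1e5, sst = rnorm(500, 22, 3),
                      noise = rnorm(500))
  f_small <- fit_sdm(d, "sst")
  f_big <- fit_sdm(d, c("sst", "noise"))
  dk <- (f_big$gam$rank - f_small$gam$rank)
  expect_lte(f_small$AIC, f_big$AIC + 2 * dk)
  expect_gte(f_big$dev_expl, f_small$dev_expl - 1e-8)
})

test_that("a dome-shaped SST response is recovered from a simulated survey", {
  sim <- simulate_dome_cells(seed = 101)
  scr <- screen_collinearity(sim$cells, c("sst", "front_z", "dshore_km",
                                          "noise"))
  cands <- enumerate_candidates(setdiff(c("sst", "front_z", "dshore_km",
                                          "noise"), attr(scr, "dropped")), scr)
  sel <- select_sdm(sim$cells, cands)
  expect_true("sst" %in% sel$best$terms)
  sweep <- partial_response(sel$best, "sst", n_grid = 400)
  peak <- sweep$value[which.max(sweep$partial)]
  expect_lt(abs(peak - 23), 1.5)
  # the pure-noise covariate is not selected
  expect_false("noise" %in% sel$best$terms)
})

test_that("model selection returns a logged comparison with sensible tie-breaks", {
  sim <- simulate_dome_cells(seed = 202)
  one <- list(list(terms = "sst", interaction = FALSE))
  sel1 <- select_sdm(sim$cells, one)
  expect_identical(sel1$best$terms, "sst")    # single candidate -> itself
  expect_true(all(c("tier", "AIC", "dev_expl", "selected") %in%
                    names(sel1$table)))

  sel2 <- select_sdm(sim$cells, list(
    list(terms = c("sst", "noise"), interaction = FALSE),
    list(terms = "sst", interaction = FALSE)))
  expect_true(sel2$best$converged)
  expect_gte(nrow(sel2$table), 1)
})

test_that("cross-validation scores by rank AUC with stratified folds", {
  # perfectly separable: AUC = 1
  d_sep <- tibble::tibble(
    presence = rep(c(0L, 1L), each = 150),
    sst = c(rnorm(150, 15, 0.5), rnorm(150, 28, 0.5)),
    effort_m2 = 1e5)
  cv <- cross_validate(d_sep, "sst", k = 5, seed = 1)
  expect_equal(cv$auc, 1)
  expect_equal(cv$fpr + cv$fnr, 0)

  # AUC from the pooled predictions equals the Mann-Whitney rank oracle
  sim <- simulate_dome_cells(seed = 303)
  cv2 <- cross_validate(sim$cells, "sst", k = 5, seed = 2)
  pr <- cv2$predictions
  r <- rank(pr$p)
  n1 <- sum(pr$presence == 1); n0 <- sum(pr$presence == 0)
  auc_rank <- (sum(r[pr$presence == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(cv2$auc, auc_rank, tolerance = 1e-10)

  # AUC is invariant under a monotone transform of the predictions
  roc2 <- pROC::roc(pr$presence, qlogis(pmin(pmax(pr$p, 1e-12), 1 - 1e-12)),
                    quiet = TRUE, direction = "<", levels = c(0, 1))
  expect_equal(as.numeric(pROC::auc(roc2)), cv2$auc, tolerance = 1e-10)

  expect_error(cross_validate(d_sep[1:8, ], "sst", k = 10), "at least")
})

test_that("null labels give AUC near one half", {
  set.seed(11)
  d <- tibble::tibble(presence = rbinom(1e4, 1, 0.3),
                      sst = rnorm(1e4, 22, 3), effort_m2 = 1e5)
  cv <- cross_validate(d, "sst", k = 10, seed = 3)
  expect_lt(abs(cv$auc - 0.5), 0.02)
})

test_that("prediction surfaces mask depth, reproduce training rows, honor SE", {
  sim <- simulate_dome_cells(seed = 404)
  fit <- fit_sdm(sim$cells, c("sst", "dshore_km"))
  surf <- predict_surface(fit, sim$env, depth_limit_m = 1835)
  deep <- dplyr::filter(sim$env, depth > 1835)
  expect_true(all(is.na(surf$p[surf$masked])))
  expect_equal(sum(surf$masked), nrow(deep))
  expect_true(all(surf$se[!surf$masked] >= 0))

  # a prediction at a training row with the same offset equals the fitted value
  row <- sim$cells[17, ]
  surf_row <- predict_surface(fit, dplyr::mutate(row, depth = 10),
                              depth_limit_m = 1835,
                              reference_effort = row$effort_m2)
  fitted_p <- as.numeric(predict(fit$gam, newdata = row, type = "response"))
  expect_equal(surf_row$p, fitted_p, tolerance = 1e-8)

  # response-scale SE agrees with a parametric bootstrap of the coefficients
  nd <- withr::with_seed(4, dplyr::slice_sample(
    dplyr::filter(sim$env, depth <= 1835, step == 1), n = 25))
  sp <- predict_surface(fit, nd, depth_limit_m = 1835)
  X <- predict(fit$gam, newdata = dplyr::mutate(nd, effort_m2 = fit$ref_effort),
               type = "lpmatrix")
  draws <- withr::with_seed(5, {
    L <- chol(fit$gam$Vp)
    b <- coef(fit$gam)
    sapply(1:1000, function(i) {
      eta <- X %*% (b + t(L) %*% rnorm(length(b))) + log(fit$ref_effort)
      plogis(as.numeric(eta))
    })
  })
  boot_se <- apply(draws, 1, sd)
  ratio <- boot_se / sp$se
  expect_true(stats::median(abs(ratio - 1)) < 0.1)
})
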