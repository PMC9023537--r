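#' Screen covariates for collinearity
#'
#' Flags unordered covariate pairs whose absolute Pearson correlation
#' exceeds `rho_max` (strictly) as forbidden from co-occurring in one model.
#' Chlorophyll-a and primary productivity are always mutually exclusive
#' regardless of their sample correlation, being two proxies of the same
#' quantity. Constant covariates are dropped from modeling with a warning.
#'
#' @param cells A `cell_table` (or any tibble).
#' @param covariates Character vector of covariate column names.
#' @param rho_max Correlation threshold (default 0.7; a pair at exactly the
#'   threshold is allowed).
#' @return A tibble `var1`, `var2`, `rho`, `forbidden`; dropped constant
#'   covariates are recorded in attribute `dropped`.
#' @export
screen_collinearity <- function(cells, covariates, rho_max = 0.7) {
  d <- tibble::as_tibble(cells)[, covariates, drop = FALSE]
  const <- vapply(d, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), logical(1))
  if (any(const)) {
    warning("constant covariate(s) excluded from modeling: ",
            paste(names(d)[const], collapse = ", "), call. = FALSE)
    d <- d[, !const, drop = FALSE]
  }
  vars <- names(d)
  pairs <- if (length(vars) >= 2) utils::combn(vars, 2, simplify = FALSE) else list()
  out <- purrr::map(pairs, function(pr) {
    ok <- stats::complete.cases(d[[pr[1]]], d[[pr[2]]])
    if (sum(ok) < 3) stop("fewer than 3 complete rows for pair ",
                          paste(pr, collapse = "/"), call. = FALSE)
    rho <- stats::cor(d[[pr[1]]][ok], d[[pr[2]]][ok])
    tibble::tibble(var1 = pr[1], var2 = pr[2], rho = rho,
                   forbidden = abs(rho) > rho_max |
                     setequal(pr, c("chla", "pp")))
  }) |> purrr::list_rbind()
  if (!length(pairs)) {
    out <- tibble::tibble(var1 = character(0), var2 = character(0),
                          rho = numeric(0), forbidden = logical(0))
  }
  attr(out, "dropped") <- names(const)[const]
  out
}

#' Enumerate admissible covariate subsets
#'
#' Builds all subsets of the covariate pool (including the intercept-only
#' model) that contain no forbidden pair; when both members of
#' `interaction` are present in a subset, a second candidate adding their
#' tensor-product interaction is included (the interaction never appears
#' without its mains).
#'
#' @param pool Character vector of covariate names.
#' @param forbidden Output of [screen_collinearity()] (or a tibble with
#'   `var1`, `var2`, `forbidden`), or `NULL`.
#' @param interaction Length-2 character vector naming the interaction pair
#'   to test (default `c("front_z", "sst")`), or `NULL` for none.
#' @return A list of candidates, each `list(terms = chr, interaction = lgl)`.
#' @export
enumerate_candidates <- function(pool, forbidden = NULL,
                                 interaction = c("front_z", "sst")) {
  if (!length(pool)) stop("empty covariate pool.", call. = FALSE)
  bad <- list()
  if (!is.null(forbidden) && nrow(forbidden)) {
    fb <- forbidden[forbidden$forbidden, , drop = FALSE]
    bad <- purrr::map2(fb$var1, fb$var2, c)
  }
  subsets <- purrr::map(0:(2^length(pool) - 1), function(mask) {
    pool[bitwAnd(mask, 2^(seq_along(pool) - 1)) > 0]
  })
  ok <- purrr::keep(subsets, function(s) {
    !any(purrr::map_lgl(bad, ~ all(.x %in% s)))
  })
  out <- purrr::map(ok, ~ list(terms = .x, interaction = FALSE))
  if (!is.null(interaction) && length(interaction) == 2) {
    with_int <- purrr::keep(ok, ~ all(interaction %in% .x))
    out <- c(out, purrr::map(with_int, ~ list(terms = .x, interaction = TRUE)))
  }
  out
}

sdm_formula <- function(terms, interaction = FALSE, k = 3,
                        int_pair = c("front_z", "sst"), penalized = FALSE) {
  fx <- if (penalized) "" else ", fx=TRUE"
  sm <- sprintf("s(%s, k=%d, bs='cr'%s)", terms, k, fx)
  if (interaction) {
    sm <- c(sm, sprintf("te(%s, %s, k=%d%s)", int_pair[1], int_pair[2], k, fx))
  }
  rhs <- paste(c("offset(log(effort_m2))", sm), collapse = " + ")
  if (!length(terms) && !interaction) rhs <- "offset(log(effort_m2)) + 1"
  stats::as.formula(paste("presence ~", rhs))
}

#' Fit an effort-offset binomial GAM
#'
#' Fits cell-day presence/absence with a logit link, `log(effort)` offset
#' and small fixed-dimension smooths: each covariate enters as a 3-knot
#' (basis dimension 3) cubic regression spline, and the optional
#' front-by-SST interaction as a tensor product of those marginal bases.
#' The tiny unpenalized basis deliberately caps each term at 2 effective
#' degrees of freedom, which curbs overprediction when extrapolating to
#' unsurveyed months while preserving dome-shaped responses.
#'
#' @param cells A `cell_table` with `presence`, `effort_m2 > 0` and the
#'   covariates.
#' @param terms Character vector of covariate names (may be empty for the
#'   intercept-only model).
#' @param interaction Add the tensor interaction for `int_pair`?
#' @param int_pair Interaction pair (default `c("front_z", "sst")`).
#' @param k Marginal basis dimension (default 3).
#' @param penalized Use penalized smooths instead of fixed df.
#' @return An object of class `sdm_fit`.
#' @export
fit_sdm <- function(cells, terms = character(0), interaction = FALSE,
                    int_pair = c("front_z", "sst"), k = 3, penalized = FALSE) {
  d <- tibble::as_tibble(cells)
  stopifnot(all(c("presence", "effort_m2") %in% names(d)))
  d <- d[d$effort_m2 > 0, , drop = FALSE]
  need <- unique(c(terms, if (interaction) int_pair))
  d <- d[stats::complete.cases(d[, c("presence", "effort_m2", need),
                                 drop = FALSE]), , drop = FALSE]
  form <- sdm_formula(terms, interaction, k, int_pair, penalized)
  g <- try(mgcv::gam(form, family = stats::binomial(), data = d,
                     method = "ML"), silent = TRUE)
  failed <- inherits(g, "try-error") || !g$converged ||
    any(!is.finite(stats::coef(g)))
  if (failed) {
    return(structure(list(terms = terms, interaction = interaction,
                          converged = FALSE,
                          label = sdm_label(terms, interaction, int_pair)),
                     class = "sdm_fit"))
  }
  ranges <- purrr::map(need, ~ range(d[[.x]]))
  names(ranges) <- need
  structure(list(
    gam = g, terms = terms, interaction = interaction, int_pair = int_pair,
    k = k, formula = form, converged = TRUE,
    AIC = stats::AIC(g),
    # the intercept-only model is the null model: 0 by definition, not
    # subject to floating-point residue
    dev_expl = if (!length(terms) && !interaction) 0 else
      100 * (1 - g$deviance / g$null.deviance),
    n = nrow(d), n_presence = sum(d$presence),
    ref_effort = exp(mean(log(d$effort_m2))),
    ranges = ranges,
    label = sdm_label(terms, interaction, int_pair)
  ), class = "sdm_fit")
}

sdm_label <- function(terms, interaction, int_pair = c("front_z", "sst")) {
  parts <- c("offset(log(effort))",
             if (interaction) paste0(int_pair[1], " x ", int_pair[2]), terms)
  paste(parts, collapse = " + ")
}

#' @export
print.sdm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sdm_fit> FAILED:", x$label, "\n"); return(invisible(x))
  }
  cat(sprintf("<sdm_fit> %s\n  n=%d (%d presences), AIC=%.1f, deviance explained=%.1f%%\n",
              x$label, x$n, x$n_presence, x$AIC, x$dev_expl))
  invisible(x)
}

#' @method tidy sdm_fit
#' @export
tidy.sdm_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(0), edf = numeric(0),
                          statistic = numeric(0), p.value = numeric(0)))
  }
  st <- summary(x$gam)$s.table
  if (is.null(st) || !nrow(st)) {
    return(tibble::tibble(term = "(Intercept)",
                          edf = 0,
                          statistic = summary(x$gam)$p.t[1],
                          p.value = summary(x$gam)$p.pv[1]))
  }
  tibble::tibble(term = rownames(st), edf = st[, "edf"],
                 statistic = st[, "Chi.sq"], p.value = st[, "p-value"])
}

#' @method glance sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(model = x$label, converged = x$converged,
                 n = x$n %||% NA_integer_,
                 AIC = x$AIC %||% NA_real_,
                 dev_expl = x$dev_expl %||% NA_real_,
                 n_terms = length(x$terms) + as.integer(isTRUE(x$interaction)))
}

#' Select a distribution model by AIC with tiered significance pruning
#'
#' Fits every candidate, takes the lowest-AIC converged model (ties go to
#' fewer terms), then builds up to three tiered reductions by iteratively
#' dropping the least significant smooth term (approximate test p > `alpha`).
#' The final choice among the AIC-best model and its tiers is by tenfold
#' cross-validated AUC when `cv_k` is set, otherwise the most-pruned tier
#' whose deviance explained falls within `dev_tol` percentage points of the
#' AIC-best model; the rule applied is recorded in the comparison table.
#'
#' @param cells A `cell_table`.
#' @param candidates List from [enumerate_candidates()].
#' @param alpha Significance threshold for pruning (default 0.05).
#' @param cv_k Folds for cross-validated AUC comparison, or `NULL` to skip.
#' @param dev_tol Deviance-explained tolerance (percentage points) for the
#'   no-CV parsimony rule.
#' @param seed Seed for CV fold assignment.
#' @param ... Passed to [fit_sdm()].
#' @return A list: `best` (the chosen `sdm_fit`), `table` (comparison of the
#'   AIC-best and tiers), `aic_table` (all candidates), `rule`.
#' @export
select_sdm <- function(cells, candidates, alpha = 0.05, cv_k = NULL,
                       dev_tol = 1, seed = 1L, ...) {
  fits <- purrr::map(candidates,
                     function(cand) fit_sdm(cells, cand$terms,
                                            cand$interaction, ...))
  ok <- purrr::keep(fits, "converged")
  if (!length(ok)) stop("no converged candidate models.", call. = FALSE)
  aic_tab <- purrr::map(ok, glance) |> purrr::list_rbind() |>
    dplyr::arrange(.data$AIC, .data$n_terms)
  aics <- purrr::map_dbl(ok, "AIC")
  nterm <- purrr::map_dbl(ok, ~ length(.x$terms) + isTRUE(.x$interaction))
  tied <- which(aics <= min(aics) + 1e-8)
  best <- ok[[tied[which.min(nterm[tied])]]]

  # tiered reductions: drop the least significant term while any p > alpha
  tiers <- list(best)
  cur <- best
  for (i in 1:3) {
    tt <- tidy(cur)
    tt <- tt[tt$term != "(Intercept)", , drop = FALSE]
    if (!nrow(tt) || all(tt$p.value <= alpha, na.rm = TRUE)) break
    worst <- tt$term[which.max(tt$p.value)]
    is_int <- grepl("^te\\(", worst)
    new_terms <- cur$terms
    new_int <- cur$interaction
    if (is_int) new_int <- FALSE
    else new_terms <- setdiff(new_terms, gsub("^s\\(|\\)$", "", worst))
    cand <- fit_sdm(cells, new_terms, new_int, ...)
    if (!cand$converged) break
    tiers <- c(tiers, list(cand))
    cur <- cand
  }

  tab <- purrr::map(tiers, glance) |> purrr::list_rbind() |>
    dplyr::mutate(tier = seq_along(tiers) - 1L, .before = 1L)
  if (!is.null(cv_k)) {
    cv <- purrr::map(tiers, function(f) {
      out <- try(cross_validate(cells, f$terms, f$interaction, k = cv_k,
                                seed = seed, ...), silent = TRUE)
      if (inherits(out, "try-error")) list(auc = NA_real_) else out
    })
    tab$cv_auc <- purrr::map_dbl(cv, "auc")
    pick <- which.max(tab$cv_auc)
    rule <- sprintf("highest %d-fold CV AUC among AIC-best and tiers", cv_k)
  } else {
    pick <- max(which(tab$dev_expl >= tab$dev_expl[1] - dev_tol))
    rule <- sprintf("most-pruned tier within %.1f pp deviance explained of the AIC-best", dev_tol)
  }
  tab$selected <- seq_len(nrow(tab)) == pick
  list(best = tiers[[pick]], table = tab, aic_table = aic_tab, rule = rule)
}

#' Stratified k-fold cross-validation of a distribution model
#'
#' Splits presences and absences separately into `k` folds (seeded), refits
#' on each training set, pools held-out predictions, and scores them by the
#' rank-based AUC. The false positive and false negative rates are reported
#' at the probability threshold maximizing Youden's J on the pooled
#' predictions.
#'
#' @param cells A `cell_table`.
#' @param terms,interaction,... Model specification as in [fit_sdm()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @return A list: `auc`, `fpr`, `fnr`, `threshold`, `predictions` (tibble
#'   of held-out `presence`, `p`, `fold`).
#' @export
cross_validate <- function(cells, terms = character(0), interaction = FALSE,
                           k = 10, seed = 1L, ...) {
  d <- tibble::as_tibble(cells)
  d <- d[d$effort_m2 > 0, , drop = FALSE]
  n1 <- sum(d$presence == 1); n0 <- sum(d$presence == 0)
  if (n1 < k || n0 < k) {
    stop(sprintf("need at least k=%d presences and absences (have %d/%d).",
                 k, n1, n0), call. = FALSE)
  }
  folds <- withr::with_seed(as.integer(seed), {
    f <- integer(nrow(d))
    f[d$presence == 1] <- sample(rep_len(seq_len(k), n1))
    f[d$presence == 0] <- sample(rep_len(seq_len(k), n0))
    f
  })
  preds <- purrr::map(seq_len(k), function(i) {
    fit <- fit_sdm(d[folds != i, , drop = FALSE], terms, interaction, ...)
    if (!fit$converged) stop("fold ", i, " did not converge.", call. = FALSE)
    held <- d[folds == i, , drop = FALSE]
    p <- as.numeric(stats::predict(fit$gam, newdata = held, type = "response"))
    tibble::tibble(presence = held$presence, p = p, fold = i)
  }) |> purrr::list_rbind()

  roc <- pROC::roc(preds$presence, preds$p, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "specificity", "sensitivity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  list(auc = as.numeric(pROC::auc(roc)),
       fpr = 1 - best$specificity, fnr = 1 - best$sensitivity,
       threshold = best$threshold, predictions = preds)
}

#' Predict a depth-masked probability-of-occurrence surface
#'
#' Evaluates the model over an environment stack at a fixed reference effort
#' (default: the geometric mean of the training efforts, which centres the
#' log-effort offset), returning per-cell probability of occurrence and its
#' standard error. Cells deeper than `depth_limit_m` are masked (the model
#' is only defined from the shoreline to the maximum depth surveyed); cells
#' with any covariate outside the training range are flagged `extrapolated`.
#'
#' @param fit A converged `sdm_fit`.
#' @param env Environment stack rows to predict for (any number of steps).
#' @param depth_limit_m Depth mask limit (m).
#' @param reference_effort Effort (m^2) at which to predict; default the
#'   geometric mean training effort.
#' @return A `prediction_surface` tibble: `step`, `cell`, `lat`, `p`, `se`,
#'   `masked`, `extrapolated`.
#' @export
predict_surface <- function(fit, env, depth_limit_m = 1835,
                            reference_effort = NULL) {
  stopifnot(inherits(fit, "sdm_fit"), isTRUE(fit$converged))
  nd <- tibble::as_tibble(env)
  if (is.null(reference_effort)) reference_effort <- fit$ref_effort
  nd$effort_m2 <- reference_effort
  pr <- stats::predict(fit$gam, newdata = nd, type = "link", se.fit = TRUE)
  p <- stats::plogis(as.numeric(pr$fit))
  se <- as.numeric(pr$se.fit) * p * (1 - p)
  masked <- nd$depth > depth_limit_m
  extrap <- rep(FALSE, nrow(nd))
  for (v in names(fit$ranges)) {
    extrap <- extrap | nd[[v]] < fit$ranges[[v]][1] | nd[[v]] > fit$ranges[[v]][2]
  }
  out <- tibble::tibble(
    step = nd$step, cell = nd$cell, lat = nd$lat,
    p = ifelse(masked, NA_real_, p), se = ifelse(masked, NA_real_, se),
    masked = masked, extrapolated = extrap & !masked)
  attr(out, "grid") <- attr(env, "grid")
  attr(out, "depth_limit_m") <- depth_limit_m
  attr(out, "reference_effort") <- reference_effort
  class(out) <- c("prediction_surface", class(out))
  out
}
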