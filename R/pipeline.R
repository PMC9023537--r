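#' Bundled demonstration configuration
#'
#' Reads the packaged demo run configuration: a 10-km planar grid, 204
#' monthly environment steps, a dome-shaped (23 deg C optimum) occurrence
#' truth with nearshore and frontal enrichment, one dual-team hazard-rate
#' survey and one single-team half-normal survey flown over the first
#' survey years, and the downstream model/validation/trend settings.
#'
#' @param path Optional path to a YAML config to read instead.
#' @return A named list of class `run_config`.
#' @export
demo_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demo_config.yaml", package = "aerialsdm")
  }
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A named list (e.g. from [yaml::read_yaml()]).
#' @return The config, invisibly classed `run_config`; errors describe the
#'   first offending field.
#' @export
validate_config <- function(cfg) {
  req <- c("seed", "grid", "environment", "truth", "surveys", "preprocess",
           "detection", "sdm", "validation", "trends")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("config is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- list(c("grid", "cell_km"), c("environment", "n_steps"),
              c("preprocess", "right_m"), c("sdm", "depth_limit_m"),
              c("detection", "n_min"))
  for (p in pos) {
    v <- cfg[[p[1]]][[p[2]]]
    if (is.null(v) || !is.numeric(v) || v <= 0) {
      stop(sprintf("config field %s$%s must be a positive number.",
                   p[1], p[2]), call. = FALSE)
    }
  }
  if (!is.null(cfg$sdm$rho_max) && (!is.numeric(cfg$sdm$rho_max) ||
                                      cfg$sdm$rho_max <= 0)) {
    stop("config field sdm$rho_max must be a positive number.", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

pipeline_stages <- c("simulate", "preprocess", "detect", "grid", "fit",
                     "predict", "ensemble", "validate", "trends")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> detection fitting -> gridding ->
#' SDM selection -> monthly prediction -> ensemble -> external validation ->
#' centroid trend analysis, writing per-stage tables (CSV), a machine-
#' readable `report.json` and a run log to `outdir`. Fully deterministic
#' given `config$seed`.
#'
#' @param config A `run_config` (see [demo_config()] / [validate_config()]).
#' @param outdir Output directory (created if needed).
#' @param until Last stage to run, one of `r paste(pipeline_stages, collapse=", ")`.
#' @param quiet Suppress progress messages.
#' @return A list with all in-memory artifacts (`env`, `surveys`, `fits`,
#'   `surfaces`, `validation`, `trends`, `report`), invisibly.
#' @export
run_pipeline <- function(config, outdir = tempfile("aerialsdm_run"),
                         until = "trends", quiet = FALSE) {
  cfg <- validate_config(config)
  until <- match.arg(until, pipeline_stages)
  n_until <- match(until, pipeline_stages)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  art <- list(config = cfg, outdir = outdir)
  report <- list(seed = cfg$seed)

  ## -- simulate -----------------------------------------------------------
  say("stage simulate: grid %dx%d, %d steps", cfg$grid$nx, cfg$grid$ny,
      cfg$environment$n_steps)
  grid <- grid_spec(cell_km = cfg$grid$cell_km, nx = cfg$grid$nx,
                    ny = cfg$grid$ny, lat0 = cfg$grid$lat0)
  sp_args <- cfg$environment[setdiff(names(cfg$environment), "n_steps")]
  season <- do.call(season_params, sp_args)
  env <- generate_environment(grid, cfg$environment$n_steps, season,
                              seed = cfg$seed)
  env <- compute_front_z(env)
  truth <- occurrence_model(
    intercept = cfg$truth$intercept, sst_opt = cfg$truth$sst_opt,
    sst_width = cfg$truth$sst_width, betas = unlist(cfg$truth$betas))
  p_true <- true_probability_surface(env, truth)

  surveys <- purrr::imap(cfg$surveys, function(sv, nm) {
    det <- detection_truth(key = sv$detection$key,
                           sigma_m = sv$detection$sigma_m,
                           shape = sv$detection$shape %||% 2.5,
                           p0 = unlist(sv$detection$p0))
    steps <- seq(sv$steps_from, sv$steps_to)
    tl <- make_tracklines(grid, steps, spacing_km = sv$spacing_km)
    sc <- survey_scenario(
      tl, teams = sv$teams, detection = det,
      record_interval_s = sv$record_interval_s %||% 10,
      strip_m = sv$strip_m %||% 600,
      density_per_km2 = sv$density_per_km2,
      seed = cfg$seed + match(nm, names(cfg$surveys)), survey_id = nm)
    simulate_survey(env, p_true, sc)
  })
  for (nm in names(surveys)) {
    utils::write.csv(surveys[[nm]]$effort,
                     file.path(outdir, paste0("effort_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(surveys[[nm]]$sightings,
                     file.path(outdir, paste0("sightings_", nm, ".csv")),
                     row.names = FALSE)
    say("  survey %s: %d segments, %d sighting rows", nm,
        nrow(surveys[[nm]]$effort), nrow(surveys[[nm]]$sightings))
  }
  art$env <- env; art$p_true <- p_true; art$surveys <- surveys
  if (n_until < 2) return(finish_run(art, report, outdir, say))

  ## -- preprocess ---------------------------------------------------------
  pp <- cfg$preprocess
  prep <- purrr::imap(surveys, function(sv, nm) {
    s <- apply_truncation(sv$sightings, left_m = pp$left_m,
                          right_m = pp$right_m,
                          team_rule = if (length(cfg$surveys[[nm]]$teams) > 1)
                            "aft_only" else "all")
    fe <- filter_effort(sv$effort, s, max_beaufort = pp$max_beaufort,
                        max_altitude_m = pp$max_altitude_m,
                        max_heading_change_deg = pp$max_heading_change_deg %||% Inf)
    say("  %s: truncation removed %d, effort filters removed %d segments",
        nm, sum(attr(s, "truncation_log")$removed), fe$n_removed)
    dual <- length(cfg$surveys[[nm]]$teams) > 1
    events <- if (dual) {
      fwd <- fe$sightings[fe$sightings$team == "forward", , drop = FALSE]
      aft <- fe$sightings[fe$sightings$team == "aft", , drop = FALSE]
      match_duplicates(fwd, aft, dt_max = pp$dt_max, dangle_max = pp$dangle_max)
    } else {
      dplyr::mutate(fe$sightings, observer_1 = TRUE, observer_2 = FALSE,
                    match = "forward_only")
    }
    list(segments = fe$segments, events = events, dual = dual)
  })
  art$prep <- prep
  if (n_until < 3) return(finish_run(art, report, outdir, say))

  ## -- detection ----------------------------------------------------------
  det_cfg <- cfg$detection
  fits <- purrr::imap(prep, function(p, nm) {
    keys <- unlist(cfg$surveys[[nm]]$key_candidates %||% list("hr", "hn"))
    cands <- purrr::map(keys, function(k) {
      try(if (p$dual) {
        fit_mrds(p$events, key = k, w = pp$right_m,
                 mr_formula = stats::as.formula(
                   cfg$surveys[[nm]]$mr_formula %||% "~ distance_m + observer"),
                 n_min = det_cfg$n_min)
      } else {
        fit_mcds(p$events, key = k, w = pp$right_m, n_min = det_cfg$n_min)
      }, silent = TRUE)
    })
    cands <- purrr::keep(cands, ~ inherits(.x, "detection_fit"))
    if (!length(cands)) stop("detection stage failed for survey ", nm,
                             call. = FALSE)
    best <- select_by_aic(cands)
    ap <- average_detection_probability(best, B = det_cfg$bootstrap_B %||% 0,
                                        seed = cfg$seed + 100)
    say("  %s: %s key selected, p-bar=%.3f (CV=%.3f)", nm, best$key, ap$p,
        ap$cv)
    list(fit = best, p = ap)
  })
  report$detection <- purrr::imap(fits, function(f, nm) {
    list(survey = nm, key = f$fit$key, type = f$fit$type,
         p_bar = f$p$p, cv = f$p$cv, AIC = f$fit$AIC,
         p0 = if (is.null(f$fit$mr)) 1 else f$fit$mr$p0_combined)
  })
  art$detection <- fits
  if (n_until < 4) return(finish_run(art, report, outdir, say))

  ## -- gridding -----------------------------------------------------------
  cell_tables <- purrr::imap(prep, function(p, nm) {
    seg <- transfer_detection(fits[[nm]]$fit, p$segments)
    alloc <- segment_to_cells(seg, grid)
    ct <- summarize_grid(alloc, p$events, seg, env)
    utils::write.csv(ct, file.path(outdir, paste0("cells_", nm, ".csv")),
                     row.names = FALSE)
    say("  %s: %d cell-days, %d presences", nm, nrow(ct), sum(ct$presence))
    ct
  })
  art$cell_tables <- cell_tables
  if (n_until < 5) return(finish_run(art, report, outdir, say))

  ## -- sdm fitting --------------------------------------------------------
  pool <- unlist(cfg$sdm$pool)
  pooled <- combine_surveys(cell_tables)
  model_inputs <- c(cell_tables, list(combined = pooled))
  sdms <- purrr::imap(model_inputs, function(ct, nm) {
    scr <- screen_collinearity(ct, pool, rho_max = cfg$sdm$rho_max)
    cands <- enumerate_candidates(setdiff(pool, attr(scr, "dropped")), scr,
                                  interaction = unlist(cfg$sdm$interaction))
    sel <- select_sdm(ct, cands, cv_k = cfg$sdm$cv_k, seed = cfg$seed + 7)
    say("  %s: selected %s (dev expl %.1f%%)", nm, sel$best$label,
        sel$best$dev_expl)
    sel
  })
  report$sdm <- purrr::imap(sdms, function(s, nm) {
    g <- glance(s$best)
    out <- list(survey = nm, model = g$model, AIC = g$AIC,
                dev_expl = g$dev_expl, rule = s$rule)
    if ("cv_auc" %in% names(s$table)) {
      out$cv_auc <- s$table$cv_auc[s$table$selected]
    }
    out
  })
  art$sdms <- sdms
  if (n_until < 6) return(finish_run(art, report, outdir, say))

  ## -- monthly surfaces ---------------------------------------------------
  dl <- cfg$sdm$depth_limit_m
  surfaces <- purrr::imap(sdms, function(s, nm) {
    predict_surface(s$best, env, depth_limit_m = dl)
  })
  art$surfaces <- surfaces
  if (n_until < 7) return(finish_run(art, report, outdir, say))

  ## -- ensemble -----------------------------------------------------------
  per_survey <- surfaces[names(cell_tables)]
  ens <- weighted_ensemble(per_survey)
  surfaces$ensemble <- ens
  utils::write.csv(ens, file.path(outdir, "surface_ensemble.csv"),
                   row.names = FALSE)
  say("  ensemble over %d surveys", length(per_survey))
  art$surfaces <- surfaces
  if (n_until < 8) return(finish_run(art, report, outdir, say))

  ## -- external validation ------------------------------------------------
  vcfg <- cfg$validation
  indep <- withr::with_seed(cfg$seed + 300, {
    pool_cells <- dplyr::filter(p_true, .data$depth <= dl)
    idx <- sample.int(nrow(pool_cells), size = vcfg$n_independent,
                      replace = TRUE, prob = pool_cells$p)
    dplyr::select(pool_cells[idx, ], "step", "cell")
  })
  validation <- purrr::imap(
    surfaces[intersect(c("combined", "ensemble"), names(surfaces))],
    function(s, nm) external_z_validation(s, indep, mode = vcfg$mode))
  report$validation <- purrr::imap(validation, function(v, nm) {
    as.list(v$summary)
  })
  for (nm in names(validation)) {
    say("  %s: mean score %.3f, t(%d)=%.1f, p=%.2g", nm,
        validation[[nm]]$summary$mean, round(validation[[nm]]$summary$df),
        validation[[nm]]$summary$statistic, validation[[nm]]$summary$p.value)
  }
  art$validation <- validation
  if (n_until < 9) return(finish_run(art, report, outdir, say))

  ## -- trends -------------------------------------------------------------
  tcfg <- cfg$trends
  trends <- purrr::imap(surfaces, function(s, nm) {
    cs <- centroid_series(s, label = nm)
    sar <- fit_sarima(cs, order = unlist(tcfg$order),
                      seasonal = unlist(tcfg$seasonal), period = tcfg$period)
    fc <- forecast_sarima(sar, horizon = tcfg$horizon)
    utils::write.csv(cs, file.path(outdir, paste0("centroids_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(fc, file.path(outdir, paste0("forecast_", nm, ".csv")),
                     row.names = FALSE)
    list(series = cs, sarima = sar, forecast = fc)
  })
  report$trends <- purrr::imap(trends, function(t, nm) {
    co <- t$sarima$coefficients
    list(model = nm,
         coefficients = purrr::transpose(as.list(co)),
         lag12_acf = stats::acf(t$series$centroid_lat, lag.max = 12,
                                plot = FALSE)$acf[13])
  })
  for (nm in names(trends)) {
    co <- trends[[nm]]$sarima$coefficients
    sma <- co[co$term == "sma1", ]
    if (nrow(sma)) {
      say("  %s: sma1=%.3f (t=%.2f, p=%.2g)", nm, sma$estimate,
          sma$statistic, sma$p.value)
    }
  }
  art$trends <- trends
  finish_run(art, report, outdir, say)
}

finish_run <- function(art, report, outdir, say) {
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("run complete: %s", outdir)
  art$report <- report
  invisible(art)
}
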