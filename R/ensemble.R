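#' Combine prediction surfaces into a (1 - SE)-weighted ensemble
#'
#' Per cell and step, component predictions are averaged with weights
#' `w_i = max(1 - SE_i, 0)`, placing more emphasis on the component with the
#' least uncertainty at that location. Cells where a component is masked
#' simply drop that component (the remaining weights renormalize); a cell is
#' null only when every component is masked or all weights are zero.
#'
#' @param surfaces Named list of `prediction_surface` tibbles on the same
#'   grid and steps.
#' @return An `ensemble_surface` tibble: `step`, `cell`, `lat`, `p`,
#'   `weight_sum`, `n_components`.
#' @export
weighted_ensemble <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1)
  keys <- purrr::map(surfaces, ~ paste(.x$step, .x$cell))
  if (length(unique(purrr::map_chr(keys, ~ paste(sort(.x), collapse = ";")))) != 1) {
    stop("surfaces are not aligned on the same step/cell grid.", call. = FALSE)
  }
  if (is.null(names(surfaces))) names(surfaces) <- paste0("m", seq_along(surfaces))
  long <- purrr::imap(surfaces, function(s, nm) {
    dplyr::transmute(tibble::as_tibble(s), .data$step, .data$cell, .data$lat,
                     component = nm, p = .data$p,
                     w = pmax(1 - .data$se, 0))
  }) |> purrr::list_rbind()
  out <- long |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::summarise(
      p = if (sum(.data$w) > 0) sum(.data$w * .data$p) / sum(.data$w) else NA_real_,
      weight_sum = sum(.data$w), n_components = dplyr::n(),
      .by = c("step", "cell", "lat")) |>
    dplyr::right_join(
      dplyr::distinct(long, .data$step, .data$cell, .data$lat),
      by = c("step", "cell", "lat")) |>
    dplyr::arrange(.data$step, .data$cell)
  attr(out, "grid") <- attr(surfaces[[1]], "grid")
  class(out) <- c("ensemble_surface", "prediction_surface", class(out))
  out
}

#' Pool cell-day tables from several surveys
#'
#' Appends survey-specific cell-day tables into one series for a pooled
#' ("combined surveys") model fit. All tables must already express effort in
#' the same swept-area units (m^2); duplicate cell-days from different
#' surveys are retained as separate rows.
#'
#' @param ... Named `cell_table` tibbles, or a single list of them.
#' @return The row-bound `cell_table` with a `survey` column.
#' @export
combine_surveys <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    names(tabs) <- paste0("survey", seq_along(tabs))
  }
  units <- purrr::map_chr(tabs, ~ attr(.x, "effort_units") %||% "m2")
  if (length(unique(units)) != 1) {
    stop("effort unit mismatch across surveys: ",
         paste(unique(units), collapse = ", "), call. = FALSE)
  }
  base_cols <- purrr::map(tabs, names)
  out <- purrr::imap(tabs, ~ dplyr::mutate(tibble::as_tibble(.x), survey = .y)) |>
    purrr::list_rbind()
  attr(out, "grid") <- attr(tabs[[1]], "grid")
  class(out) <- c("cell_table", class(out))
  out
}

#' External validation against independent presence-only sightings
#'
#' For each independent sighting, the model prediction at its cell and day is
#' divided by that day's domain-wide median prediction over valid-depth
#' (unmasked) cells, and the ratio is centred at zero by subtracting one:
#' `s_i = p_i / median_day - 1`. Positive scores mean the model ranks the
#' sighted location above the typical available habitat that day. The
#' summary reports the proportion of positive scores, the mean with its 95%
#' confidence interval, and a one-sample t-test (one-sided, mean > 0 by
#' default). Sightings without a valid (unmasked, finite) prediction are
#' dropped and counted.
#'
#' @param surface A `prediction_surface` (or ensemble) covering the sighting
#'   steps.
#' @param sightings Tibble with `step` and either `cell` or `x_km`/`y_km`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param mode `"median_ratio"` (default) or `"zscore"`: the latter first
#'   standardizes each day's surface to zero mean and unit SD and scores a
#'   sighting by its standardized prediction minus the daily median of the
#'   standardized values.
#' @return A list of class `validation_result`: `scores` (per-sighting
#'   tibble), `summary` (one-row tibble: n, n_dropped, prop_positive, mean,
#'   conf.low, conf.high, statistic, df, p.value), `mode`.
#' @export
external_z_validation <- function(surface, sightings,
                                  alternative = c("greater", "two.sided"),
                                  mode = c("median_ratio", "zscore")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  surf <- tibble::as_tibble(surface)
  sig <- tibble::as_tibble(sightings)
  if (!"cell" %in% names(sig)) {
    grid <- attr(surface, "grid")
    if (is.null(grid)) stop("sightings lack `cell` and surface has no grid.",
                            call. = FALSE)
    sig$cell <- locate_cell(grid, sig$x_km, sig$y_km)
  }

  daily <- surf |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::summarise(ref = stats::median(.data$p),
                     mu = mean(.data$p), sd = stats::sd(.data$p),
                     .by = "step")

  scored <- sig |>
    dplyr::mutate(.sid = dplyr::row_number()) |>
    dplyr::left_join(dplyr::select(surf, "step", "cell", "p"),
                     by = c("step", "cell")) |>
    dplyr::left_join(daily, by = "step")
  n_dropped <- sum(is.na(scored$p) | is.na(scored$ref) |
                     scored$ref == 0 | (mode == "zscore" &
                                          (is.na(scored$sd) | scored$sd == 0)))
  scored <- scored[!(is.na(scored$p) | is.na(scored$ref) | scored$ref == 0), ,
                   drop = FALSE]
  if (mode == "median_ratio") {
    scored$score <- scored$p / scored$ref - 1
  } else {
    scored <- scored[!is.na(scored$sd) & scored$sd > 0, , drop = FALSE]
    z <- (scored$p - scored$mu) / scored$sd
    zref <- (scored$ref - scored$mu) / scored$sd
    scored$score <- z - zref
  }
  if (!nrow(scored)) stop("no sighting maps to a valid prediction.", call. = FALSE)

  tt <- if (nrow(scored) >= 2 && stats::sd(scored$score) > 0) {
    stats::t.test(scored$score, mu = 0, alternative = alternative)
  } else NULL
  ci <- if (nrow(scored) >= 2 && stats::sd(scored$score) > 0) {
    stats::t.test(scored$score, mu = 0, alternative = "two.sided")$conf.int
  } else c(NA_real_, NA_real_)

  summary <- tibble::tibble(
    n = nrow(scored), n_dropped = n_dropped,
    prop_positive = mean(scored$score > 0),
    mean = mean(scored$score),
    conf.low = ci[1], conf.high = ci[2],
    statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p.value = if (is.null(tt)) NA_real_ else tt$p.value)

  structure(list(scores = dplyr::select(scored, ".sid", "step", "cell",
                                        "p", "ref", "score"),
                 summary = summary, mode = mode, alternative = alternative),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<validation_result %s> n=%d (dropped %d), %.1f%% positive, mean=%.3f (95%% CI %.3f-%.3f), t(%d)=%.2f, p=%.3g\n",
              x$mode, s$n, s$n_dropped, 100 * s$prop_positive, s$mean,
              s$conf.low, s$conf.high, round(s$df), s$statistic, s$p.value))
  invisible(x)
}

#' @method tidy validation_result
#' @export
tidy.validation_result <- function(x, ...) x$summary
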