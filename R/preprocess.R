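#' Convert clinometer angles to perpendicular sighting distances
#'
#' Aerial observers measure the angle from the vertical to the animal with a
#' clinometer; the perpendicular sighting distance follows from the flight
#' altitude as `PSD = tan(theta) * altitude`.
#'
#' @param theta_deg Angle(s) from vertical, degrees, in `[0, 90)`.
#' @param altitude_m Flight altitude(s), metres, > 0.
#' @return Perpendicular distance(s) in metres.
#' @examples
#' angle_to_distance(45, 182)   # 182 m
#' @export
angle_to_distance <- function(theta_deg, altitude_m) {
  if (any(theta_deg < 0 | theta_deg >= 90)) {
    stop("`theta_deg` must lie in [0, 90).", call. = FALSE)
  }
  if (any(altitude_m <= 0)) stop("`altitude_m` must be positive.", call. = FALSE)
  tan(theta_deg * pi / 180) * altitude_m
}

#' @rdname angle_to_distance
#' @param distance_m Perpendicular distance(s), metres, >= 0.
#' @export
distance_to_angle <- function(distance_m, altitude_m) {
  if (any(distance_m < 0)) stop("`distance_m` must be >= 0.", call. = FALSE)
  if (any(altitude_m <= 0)) stop("`altitude_m` must be positive.", call. = FALSE)
  atan(distance_m / altitude_m) * 180 / pi
}

#' Truncate sightings by perpendicular distance
#'
#' Applies left and right distance truncation before detection-function
#' fitting. Under `team_rule = "aft_only"` (the dual-observer default,
#' reflecting the restricted downward view of an aft belly/bubble team) the
#' left truncation removes only aft-team sightings; `"all"` applies it to
#' every team. Bounds are left-open/right-closed: a sighting exactly at the
#' right truncation distance is retained, one exactly at the left bound is
#' removed along with everything closer.
#'
#' @param sightings Tibble with columns `theta_deg` + `altitude_m` (or a
#'   precomputed `distance_m`) and `team`.
#' @param left_m Left truncation distance (default 3.2 m, applied per
#'   `team_rule`).
#' @param right_m Right truncation distance (default 300 m).
#' @param team_rule `"aft_only"` or `"all"`.
#' @return The filtered tibble with a `distance_m` column; removal counts are
#'   attached as attribute `truncation_log` and messaged.
#' @export
apply_truncation <- function(sightings, left_m = 3.2, right_m = 300,
                             team_rule = c("aft_only", "all")) {
  team_rule <- match.arg(team_rule)
  if (left_m < 0 || right_m <= left_m) {
    stop("need 0 <= left_m < right_m.", call. = FALSE)
  }
  s <- tibble::as_tibble(sightings)
  if (!"distance_m" %in% names(s)) {
    s$distance_m <- angle_to_distance(s$theta_deg, s$altitude_m)
  }
  left_hit <- s$distance_m <= left_m
  if (team_rule == "aft_only") left_hit <- left_hit & s$team == "aft"
  right_hit <- s$distance_m > right_m
  keep <- !(left_hit | right_hit)
  log <- tibble::tibble(
    rule = c(sprintf("left <= %.1f m (%s)", left_m, team_rule),
             sprintf("right > %.0f m", right_m)),
    removed = c(sum(left_hit & !right_hit), sum(right_hit))
  )
  out <- s[keep, , drop = FALSE]
  attr(out, "truncation_log") <- log
  out
}

# minimal circular difference between headings in degrees
heading_diff <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

#' Filter effort and sightings by survey conditions
#'
#' Retains only effort flown in usable conditions: altitude at or below
#' `max_altitude_m`, Beaufort sea state at or below `max_beaufort`, and (when
#' `max_heading_change_deg` is finite) drops waypoints/segments whose heading
#' deviates from the previous retained segment's heading by more than the
#' threshold — the standard way of excising off-track loops from trackline
#' logs. Heading change uses the minimal circular difference. Sightings on
#' removed segments are dropped with the effort.
#'
#' @param segments Effort tibble with `segment`, `altitude_m`, `beaufort`,
#'   `heading` and (for the heading rule) a within-flight ordering given by
#'   `step` then `segment`.
#' @param sightings Optional sightings tibble carrying a `segment` column.
#' @param max_beaufort,max_altitude_m,max_heading_change_deg Filter
#'   thresholds; set any to `Inf` to disable.
#' @return A list with `segments`, `sightings` and a `log` tibble of removal
#'   counts per rule.
#' @export
filter_effort <- function(segments, sightings = NULL, max_beaufort = 4,
                          max_altitude_m = 366, max_heading_change_deg = 20) {
  seg <- tibble::as_tibble(segments)
  n0 <- nrow(seg)
  drop_beaufort <- seg$beaufort > max_beaufort
  drop_alt <- seg$altitude_m > max_altitude_m
  seg1 <- seg[!(drop_beaufort | drop_alt), , drop = FALSE]

  drop_heading <- 0L
  if (is.finite(max_heading_change_deg) && nrow(seg1) > 1) {
    seg1 <- dplyr::arrange(seg1, dplyr::across(dplyr::any_of(c("step", "segment"))))
    keep <- rep(TRUE, nrow(seg1))
    grp <- if ("step" %in% names(seg1)) seg1$step else rep(1L, nrow(seg1))
    last_h <- NA_real_; last_g <- NA
    for (i in seq_len(nrow(seg1))) {
      if (!identical(grp[i], last_g)) { last_h <- seg1$heading[i]; last_g <- grp[i]; next }
      if (heading_diff(seg1$heading[i], last_h) > max_heading_change_deg) {
        keep[i] <- FALSE
      } else {
        last_h <- seg1$heading[i]
      }
    }
    drop_heading <- sum(!keep)
    seg1 <- seg1[keep, , drop = FALSE]
  }

  log <- tibble::tibble(
    rule = c(sprintf("beaufort > %s", max_beaufort),
             sprintf("altitude > %s m", max_altitude_m),
             sprintf("heading change > %s deg", max_heading_change_deg)),
    removed = c(sum(drop_beaufort), sum(drop_alt & !drop_beaufort), drop_heading)
  )

  sig <- sightings
  if (!is.null(sig) && "segment" %in% names(sig)) {
    sig <- dplyr::semi_join(tibble::as_tibble(sig), seg1, by = "segment")
  }
  list(segments = seg1, sightings = sig, log = log,
       n_removed = n0 - nrow(seg1))
}

#' Match forward- and aft-team sightings into duplicate events
#'
#' Reconciles two independent observer streams without shared animal ids: an
#' aft sighting matches a forward sighting when it records an equal number of
#' animals, on the same side of the aircraft, within `dt_max` seconds, and
#' with an angle difference strictly below `dangle_max` degrees. Candidate
#' pairs are resolved greedily, ordered by time difference then angle
#' difference, one-to-one. Aft sightings falling outside the aft team's
#' visible angle range given the forward angle can be excluded via
#' `visibility`.
#'
#' @param forward,aft Sighting tibbles (same flight, time-sorted) with
#'   `time_s`, `side`, `theta_deg`, `size`.
#' @param dt_max Maximum absolute time difference, seconds (inclusive).
#' @param dangle_max Maximum angle difference, degrees (exclusive).
#' @param visibility Optional function `(theta_fwd) -> logical`, TRUE when
#'   the aft team could have seen an animal at that forward angle; forward
#'   sightings failing it are flagged `aft_invisible` and never matched.
#' @return A tibble with one row per event: columns of the source sighting,
#'   plus `observer_1`/`observer_2` detection indicators (forward/aft) and
#'   `match` (`"both"`, `"forward_only"`, `"aft_only"`).
#' @export
match_duplicates <- function(forward, aft, dt_max = 15, dangle_max = 15,
                             visibility = NULL) {
  fwd <- tibble::as_tibble(forward)
  aft <- tibble::as_tibble(aft)
  if (nrow(fwd) && nrow(aft) &&
      "survey_id" %in% names(fwd) && "survey_id" %in% names(aft) &&
      length(union(unique(fwd$survey_id), unique(aft$survey_id))) > 1) {
    stop("forward and aft tables mix different surveys/flights.", call. = FALSE)
  }
  fwd$aft_invisible <- if (is.null(visibility)) FALSE else !visibility(fwd$theta_deg)

  cand <- NULL
  if (nrow(fwd) && nrow(aft)) {
    cand <- tidyr::expand_grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(aft))) |>
      dplyr::mutate(
        dt = abs(fwd$time_s[.data$i] - aft$time_s[.data$j]),
        dangle = abs(fwd$theta_deg[.data$i] - aft$theta_deg[.data$j]),
        ok = .data$dt <= dt_max & .data$dangle < dangle_max &
          fwd$side[.data$i] == aft$side[.data$j] &
          fwd$size[.data$i] == aft$size[.data$j] &
          !fwd$aft_invisible[.data$i]
      ) |>
      dplyr::filter(.data$ok) |>
      dplyr::arrange(.data$dt, .data$dangle)
  }

  pair_f <- integer(0); pair_a <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    used_f <- logical(nrow(fwd)); used_a <- logical(nrow(aft))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_f[i] && !used_a[j]) {
        used_f[i] <- TRUE; used_a[j] <- TRUE
        pair_f <- c(pair_f, i); pair_a <- c(pair_a, j)
      }
    }
  }

  f_evt <- fwd |>
    dplyr::mutate(observer_1 = TRUE,
                  observer_2 = seq_len(dplyr::n()) %in% pair_f,
                  match = ifelse(.data$observer_2, "both", "forward_only"))
  a_only <- aft[setdiff(seq_len(nrow(aft)), pair_a), , drop = FALSE]
  if (nrow(a_only)) {
    a_only$aft_invisible <- FALSE
    a_only$observer_1 <- FALSE
    a_only$observer_2 <- TRUE
    a_only$match <- "aft_only"
  }
  dplyr::bind_rows(f_evt, a_only)
}
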