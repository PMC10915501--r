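# Rule-based classification of westward relocation-flight departures:
# four criteria (detection gap, last fix outside the core area, final-track
# straightness, westward over the sea) plus exclusion of pass-through
# tracks, and the cut-off-date accounting of departure proportions.

one_tag <- function(track) {
  tags <- unique(track$tag_id)
  if (length(tags) != 1) {
    abort("expected a single-tag track", class = "knotflight_identity_error")
  }
  tags
}

# vectorized bearing that returns NA for zero-length segments
bearing_na <- function(x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  ifelse(dx == 0 & dy == 0, NA_real_, (atan2(dx, dy) * 180 / pi) %% 360)
}

tag_detections <- function(detections, tag) {
  if (is.null(detections) || !nrow(detections)) {
    return(as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))
  }
  if (!"tag_id" %in% names(detections)) {
    abort("detection log needs a tag_id column",
          class = "knotflight_schema_error")
  }
  detections$t[detections$tag_id == tag]
}

#' Detection-gap criterion
#'
#' TRUE iff the bird is not detected more than `gap` hours after its last
#' localization — continuing detections mean the bird is still in the
#' tracking area and did not depart.
#'
#' @param track Single-tag localization tibble.
#' @param detections Detection tibble (`tag_id`, `t`); other tags are
#'   ignored.
#' @param gap Hours, default 2 (strict: a detection exactly at the bound
#'   still passes).
#' @return Logical.
#' @export
criterion_detection_gap <- function(track, detections, gap = 2) {
  tag <- one_tag(track)
  det <- tag_detections(detections, tag)
  if (!length(det)) return(TRUE)
  max(as.numeric(det)) <= max(as.numeric(track$t)) + gap * 3600
}

#' Outside-core criterion
#'
#' TRUE iff the last fix lies strictly outside the core tracking area
#' (a fix on the boundary counts as inside).
#'
#' @param track Single-tag localization tibble.
#' @param regions A [region_set()].
#' @return Logical.
#' @export
criterion_outside_core <- function(track, regions) {
  one_tag(track)
  i <- which.max(as.numeric(track$t))
  !point_in_polygon(track$x[i], track$y[i], regions$core_area)
}

#' Final-window straightness criterion
#'
#' Bearings between consecutive fixes in the last `window` minutes of the
#' track must all turn by less than `max_turn` degrees. Needs at least 3
#' fixes in the window; fewer is an insufficient-data verdict, returned
#' as `NA`.
#'
#' @param track Single-tag localization tibble, time-ordered.
#' @param window Minutes, default 20.
#' @param max_turn Degrees, default 90 (strict: a turn of exactly 90
#'   fails).
#' @return TRUE, FALSE, or NA (insufficient fixes in the window).
#' @export
criterion_straightness <- function(track, window = 20, max_turn = 90) {
  one_tag(track)
  track <- arrange(track, .data$t)
  tmax <- max(as.numeric(track$t))
  w <- track[as.numeric(track$t) >= tmax - window * 60, , drop = FALSE]
  if (nrow(w) < 3) return(NA)
  b <- bearing_na(w$x[-nrow(w)], w$y[-nrow(w)], w$x[-1], w$y[-1])
  b <- b[!is.na(b)] # zero-length segments carry no direction
  if (length(b) < 2) return(TRUE)
  turns <- angular_difference(b[-length(b)], b[-1])
  all(turns < max_turn)
}

#' Westward-over-sea criterion
#'
#' TRUE iff the last fix lies in the sea region and the bearing of the
#' final segment falls in the westward interval (inclusive at both ends).
#'
#' @param track Single-tag localization tibble with >= 2 fixes.
#' @param regions A [region_set()].
#' @return Logical.
#' @export
criterion_westward_over_sea <- function(track, regions) {
  one_tag(track)
  track <- arrange(track, .data$t)
  n <- nrow(track)
  if (n < 2) return(FALSE)
  over_sea <- point_in_polygon(track$x[n], track$y[n], regions$sea_region)
  fb <- bearing_na(track$x[n - 1], track$y[n - 1], track$x[n], track$y[n])
  if (is.na(fb)) return(FALSE) # no movement on the final segment
  over_sea && fb >= regions$westward_range[1] && fb <= regions$westward_range[2]
}

#' Pass-through exclusion
#'
#' TRUE (exclude) iff the first fix is outside the core area and the
#' first segment speed exceeds `transit_speed` — the bird entered the
#' tracking area already in directed flight, so its take-off was not
#' observed.
#'
#' @param track Single-tag localization tibble.
#' @param regions A [region_set()].
#' @param transit_speed m/s, default 5.
#' @return Logical.
#' @export
exclude_passthrough <- function(track, regions, transit_speed = 5) {
  one_tag(track)
  track <- arrange(track, .data$t)
  outside <- !point_in_polygon(track$x[1], track$y[1], regions$core_area)
  if (!outside || nrow(track) < 2) return(FALSE)
  v1 <- segment_speed(track$x[1], track$y[1], track$t[1],
                      track$x[2], track$y[2], track$t[2])
  v1 > transit_speed
}

# walk backwards from the last fix through the terminal directed run:
# segments faster than transit_speed with successive bearing changes below
# max_turn; returns the index of the run's first fix
terminal_run_start <- function(track, transit_speed = 5, max_turn = 90) {
  n <- nrow(track)
  v <- incoming_speeds(track$t, track$x, track$y)
  n1 <- n - 1
  # stationary (zero-length) segments get an NA bearing; they terminate the
  # run via the speed test before the bearing is ever compared
  b <- c(NA_real_, bearing_na(track$x[seq_len(n1)], track$y[seq_len(n1)],
                              track$x[-1], track$y[-1]))
  j <- n
  while (j >= 2 && !is.na(v[j]) && v[j] > transit_speed) {
    if (j < n && angular_difference(b[j], b[j + 1]) >= max_turn) break
    j <- j - 1
  }
  j
}

#' Classify one track as a departure or not
#'
#' Applies the four departure criteria and the pass-through exclusion.
#' For a departure, the departure time is the first fix of the terminal
#' directed segment, found by walking backwards from the last fix while
#' segment speeds exceed `transit_speed` and successive bearing changes
#' stay below `max_turn`.
#'
#' @param track Single-tag localization tibble (preprocessed).
#' @param detections Detection tibble.
#' @param regions A [region_set()].
#' @param gap,window,max_turn,transit_speed Rule thresholds (defaults 2 h,
#'   20 min, 90 deg, 5 m/s).
#' @return One-row tibble: `tag_id`, `departed`, `departure_time`, `x`,
#'   `y`, `final_bearing`, the four criterion flags, `passthrough`, and a
#'   `reason` code for rejections.
#' @export
classify_departure <- function(track, detections, regions, gap = 2,
                               window = 20, max_turn = 90,
                               transit_speed = 5) {
  tag <- one_tag(track)
  track <- arrange(track, .data$t)
  n <- nrow(track)
  c1 <- criterion_detection_gap(track, detections, gap)
  c2 <- criterion_outside_core(track, regions)
  c3 <- criterion_straightness(track, window, max_turn)
  c4 <- if (n >= 2) criterion_westward_over_sea(track, regions) else FALSE
  pt <- exclude_passthrough(track, regions, transit_speed)
  reason <- if (pt) {
    "pass_through"
  } else if (is.na(c3)) {
    "insufficient_fixes_in_window"
  } else if (!c1) {
    "detections_continue"
  } else if (!c2) {
    "last_fix_in_core"
  } else if (!c3) {
    "track_not_straight"
  } else if (!c4) {
    "not_westward_over_sea"
  } else {
    NA_character_
  }
  departed <- is.na(reason)
  if (departed) {
    j <- terminal_run_start(track, transit_speed, max_turn)
    tibble(tag_id = tag, departed = TRUE, departure_time = track$t[j],
           x = track$x[j], y = track$y[j],
           final_bearing = bearing_na(track$x[n - 1], track$y[n - 1],
                                      track$x[n], track$y[n]),
           gap_ok = c1, outside_core = c2, straight = c3, westward_sea = c4,
           passthrough = pt, reason = NA_character_)
  } else {
    tibble(tag_id = tag, departed = FALSE,
           departure_time = as.POSIXct(NA, tz = "UTC"),
           x = NA_real_, y = NA_real_, final_bearing = NA_real_,
           gap_ok = c1, outside_core = c2,
           straight = ifelse(is.na(c3), NA, c3), westward_sea = c4,
           passthrough = pt, reason = reason)
  }
}

#' Classify every tag in a localization table
#'
#' @param tracks Localization tibble (`tag_id`, `t`, `x`, `y`).
#' @param detections Detection tibble (`tag_id`, `t`).
#' @param regions A [region_set()].
#' @param ... Thresholds passed to [classify_departure()].
#' @return Tibble with one row per tag (see [classify_departure()]).
#' @export
classify_departures <- function(tracks, detections, regions, ...) {
  check_track_cols(tracks)
  tracks %>%
    arrange(.data$tag_id, .data$t) %>%
    group_by(.data$tag_id) %>%
    group_split() %>%
    map(function(tr) classify_departure(tr, detections, regions, ...)) %>%
    list_rbind()
}

#' Empirical cut-off date
#'
#' The smallest date by which at least a fraction `q` of all departures
#' had occurred (inverse empirical CDF).
#'
#' @param departure_dates Vector of `Date`s (or coercible).
#' @param q Quantile in (0, 1], default 0.95.
#' @return A `Date`.
#' @export
cutoff_date <- function(departure_dates, q = 0.95) {
  d <- sort(as.Date(departure_dates))
  if (!length(d)) {
    abort("no departure dates", class = "knotflight_nodata_error")
  }
  if (q <= 0 || q > 1) {
    abort("q must be in (0, 1]", class = "knotflight_parameter_error")
  }
  d[ceiling(q * length(d))]
}

#' Departure proportions at the cut-off date
#'
#' Counts departures on or before the cut-off against tags still active
#' in the study area at the cut-off, the denominator convention used for
#' season-level departure percentages.
#'
#' @param departure_dates Dates of classified departures.
#' @param last_active Per-tag last-activity dates of the non-departing
#'   tags (a tag counts as remaining if still active at the cut-off).
#' @param cutoff The cut-off `Date`.
#' @return One-row tibble: `n_departed`, `n_remaining`, `pct_departed`
#'   (percent, 1 decimal).
#' @export
departure_proportions <- function(departure_dates, last_active, cutoff) {
  cutoff <- as.Date(cutoff)
  n_dep <- sum(as.Date(departure_dates) <= cutoff)
  n_rem <- sum(as.Date(last_active) >= cutoff)
  if (n_dep + n_rem == 0) {
    abort("no departed and no remaining tags at the cut-off",
          class = "knotflight_nodata_error")
  }
  tibble(n_departed = n_dep, n_remaining = n_rem,
         pct_departed = round(100 * n_dep / (n_dep + n_rem), 1))
}
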