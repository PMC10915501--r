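# Synthetic movement tracks and detection logs with known class labels:
# residents (confined correlated walks), departers (resident behaviour
# followed by a straight outbound flight ending over the sea) and
# pass-through birds (already in directed flight when first localized).

# confined random walk inside a polygon; returns matrix [n, 2]
confined_walk <- function(n, polygon, start_xy, step_sd, max_tries = 60) {
  out <- matrix(NA_real_, n, 2)
  out[1, ] <- start_xy
  cx <- mean(polygon$x); cy <- mean(polygon$y)
  for (i in seq_len(n - 1)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- out[i, ] + rnorm(2, 0, step_sd)
      if (point_in_polygon(cand[1], cand[2], polygon)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      # polygon too tight for the step scale: drift towards the centroid
      cand <- out[i, ] + 0.2 * (c(cx, cy) - out[i, ])
      if (!point_in_polygon(cand[1], cand[2], polygon)) {
        abort("core polygon too small for the walk step scale",
              class = "knotflight_generation_error")
      }
    }
    out[i + 1, ] <- cand
  }
  out
}

random_point_in_polygon <- function(polygon, margin = 0.2) {
  rx <- range(polygon$x); ry <- range(polygon$y)
  shrink <- function(r) r + c(1, -1) * margin * diff(r)
  rx <- shrink(rx); ry <- shrink(ry)
  repeat {
    p <- c(runif(1, rx[1], rx[2]), runif(1, ry[1], ry[2]))
    if (point_in_polygon(p[1], p[2], polygon)) return(p)
  }
}

#' Simulate tracks, detection logs and class labels
#'
#' Residents perform a confined random walk inside the core polygon for
#' the whole season and are detected at every fix. Departing birds behave
#' as residents until their departure time, then fly straight outbound at
#' the scenario's flight speed and bearing until well over the sea; their
#' detections stop with their last localization. Pass-through birds enter
#' already in directed flight, with their first fix outside the core
#' area, and cross westward. Every localization is perturbed with
#' isotropic Gaussian error and carries its error sd.
#'
#' @param scenario A [sim_scenario()].
#' @param regions A [region_set()] (default [default_regions()]).
#' @param departure_times Optional POSIXct vector of true departure times
#'   for the departing birds (length `n_departing`); drawn uniformly over
#'   the interior of the season if omitted.
#' @param flight_minutes Outbound flight duration (default 40 min, which
#'   at the default speed ends ~43 km out, over the sea region).
#' @param resident_step_sd Per-axis step sd of the confined walk, metres
#'   per fix (default 80).
#' @param seed Optional integer; defaults to the scenario seed.
#' @return A list with class `sim_tracks`: `tracks` (tag_id, t, x, y, sd),
#'   `detections` (tag_id, t), `labels` (tag_id, class,
#'   departure_time).
#' @export
sim_tracks <- function(scenario, regions = default_regions(),
                       departure_times = NULL, flight_minutes = 40,
                       resident_step_sd = 80, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed %||% scenario$seed)
  core <- regions$core_area
  dt <- scenario$fix_interval
  season <- seq(scenario$start, scenario$end, by = dt)
  n_flight <- ceiling(flight_minutes * 60 / dt)
  brad <- deg2rad(scenario$flight_bearing)
  vstep <- scenario$flight_speed * dt * c(sin(brad), cos(brad))

  tracks <- list(); detections <- list(); labels <- list()
  add_bird <- function(tag, t, xy, detect_t, class, dep_time) {
    noise <- matrix(rnorm(2 * length(t), 0, scenario$loc_error_sd),
                    ncol = 2)
    tracks[[tag]] <<- tibble(
      tag_id = tag, t = t,
      x = xy[, 1] + noise[, 1], y = xy[, 2] + noise[, 2],
      sd = rep(scenario$loc_error_sd, length(t))
    )
    detections[[tag]] <<- tibble(tag_id = tag, t = detect_t)
    labels[[tag]] <<- tibble(tag_id = tag, class = class,
                             departure_time = dep_time)
  }

  for (i in seq_len(scenario$n_resident)) {
    tag <- sprintf("res%03d", i)
    xy <- confined_walk(length(season), core,
                        random_point_in_polygon(core), resident_step_sd)
    add_bird(tag, season, xy, season, "resident",
             as.POSIXct(NA, tz = "UTC"))
  }

  if (scenario$n_departing > 0) {
    if (is.null(departure_times)) {
      lo <- as.numeric(scenario$start) + 86400
      hi <- as.numeric(scenario$end) - (flight_minutes + 30) * 60
      if (hi <= lo) {
        abort("season too short for departures",
              class = "knotflight_generation_error")
      }
      departure_times <- as_utc(sort(runif(scenario$n_departing, lo, hi)))
    }
    if (length(departure_times) != scenario$n_departing) {
      abort("departure_times length must equal n_departing",
            class = "knotflight_parameter_error")
    }
    for (i in seq_len(scenario$n_departing)) {
      tag <- sprintf("dep%03d", i)
      dep <- as_utc(departure_times[i])
      pre_t <- season[season < dep]
      if (length(pre_t) < 5) {
        abort("departure time too close to season start",
              class = "knotflight_generation_error")
      }
      pre_xy <- confined_walk(length(pre_t), core,
                              random_point_in_polygon(core),
                              resident_step_sd)
      fl_t <- dep + dt * seq(0, n_flight)
      takeoff <- pre_xy[nrow(pre_xy), ]
      fl_xy <- cbind(takeoff[1] + vstep[1] * seq(0, n_flight),
                     takeoff[2] + vstep[2] * seq(0, n_flight))
      t_all <- c(pre_t, fl_t)
      add_bird(tag, t_all, rbind(pre_xy, fl_xy), t_all, "departing", dep)
    }
  }

  for (i in seq_len(scenario$n_passthrough)) {
    tag <- sprintf("pas%03d", i)
    # start outside the core on its eastern side, already in flight
    x0 <- max(core$x) + 1000 + runif(1, 0, 500)
    y0 <- runif(1, min(core$y), max(core$y))
    t0 <- scenario$start + runif(1, 3600, as.numeric(
      scenario$end - scenario$start, units = "secs") - 7200)
    n_cross <- ceiling((x0 - min(regions$sea_region$x) * 0.6) /
                         abs(vstep[1]))
    tt <- t0 + dt * seq(0, n_cross)
    xy <- cbind(x0 + vstep[1] * seq(0, n_cross),
                y0 + vstep[2] * seq(0, n_cross))
    add_bird(tag, tt, xy, tt, "passthrough", as.POSIXct(NA, tz = "UTC"))
  }

  structure(list(tracks = list_rbind(unname(tracks)),
                 detections = list_rbind(unname(detections)),
                 labels = list_rbind(unname(labels))),
            class = "sim_tracks")
}
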