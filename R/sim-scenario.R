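# Scenario and ground-truth selection objects for the simulator.

#' Simulation scenario
#'
#' Describes a synthetic tracking season: how many resident, departing and
#' pass-through birds, the tracking interval and cadence, localization
#' noise, and the outbound flight kinematics.
#'
#' @param n_resident,n_departing,n_passthrough Bird counts (>= 0).
#' @param start,end Season interval (POSIXct or coercible to UTC).
#' @param fix_interval Seconds between localizations (default 60).
#' @param loc_error_sd Gaussian localization error sd in metres
#'   (default 25, typical of regional reverse-GPS systems).
#' @param flight_speed Outbound flight speed in m/s (default 18, a
#'   plausible red-knot transit speed well below the 100 m/s filter).
#' @param flight_bearing Outbound compass bearing in degrees (default 262,
#'   roughly west-south-west towards the Wash).
#' @param site_lat,site_lon Reference coordinates of the planar origin,
#'   used only for solar computation (defaults: the Griend area).
#' @param seed Integer seed stored with the scenario.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_resident = 10, n_departing = 5,
                         n_passthrough = 2,
                         start = "2019-09-01", end = "2019-09-15",
                         fix_interval = 60, loc_error_sd = 25,
                         flight_speed = 18, flight_bearing = 262,
                         site_lat = 53.25, site_lon = 5.25, seed = 1) {
  iv <- check_interval(start, end)
  if (any(c(n_resident, n_departing, n_passthrough) < 0) ||
      fix_interval <= 0 || loc_error_sd < 0 || flight_speed <= 0 ||
      flight_bearing < 0 || flight_bearing >= 360) {
    abort("invalid scenario parameters", class = "knotflight_parameter_error")
  }
  structure(list(
    n_resident = as.integer(n_resident),
    n_departing = as.integer(n_departing),
    n_passthrough = as.integer(n_passthrough),
    start = iv$start, end = iv$end,
    fix_interval = fix_interval, loc_error_sd = loc_error_sd,
    flight_speed = flight_speed, flight_bearing = flight_bearing,
    site_lat = site_lat, site_lon = site_lon, seed = as.integer(seed)
  ), class = "sim_scenario")
}

#' Default study-region polygons
#'
#' A square core tracking area centred on the planar origin and a large
#' sea rectangle to its west, in metres, sized so that a simulated
#' outbound flight of half an hour or more ends over the sea.
#'
#' @return A [region_set()].
#' @export
default_regions <- function() {
  region_set(
    core_area = rect_polygon(-4000, 4000, -4000, 4000),
    sea_region = rect_polygon(-80000, -5000, -50000, 25000)
  )
}

#' Ground-truth departure-time selection
#'
#' The known selection function used to draw synthetic departure times:
#' linear effects on wind assistance, cloud cover, pressure change and
#' rain, plus Gaussian bumps in time relative to sunset and to high tide.
#' Defaults mirror the magnitudes reported for the real system (tailwind
#' selection ~0.3 per m/s, cloud avoidance ~-0.2 per okta, activity peaks
#' ~108 min after sunset and ~238 min before high tide).
#'
#' @param beta_wind Per m/s of wind assistance (default 0.3).
#' @param beta_cloud Per okta (default -0.2).
#' @param beta_dpressure Per mb of 1-h pressure change (default 0).
#' @param beta_rain Per 0.1 mm/h of rain (default 0).
#' @param sunset_peak Minutes relative to sunset at maximum selection
#'   (default 108).
#' @param tide_peak Minutes relative to high tide at maximum selection
#'   (default -238).
#' @param smooth_scales Length-2 positive widths (minutes) of the sunset
#'   and tide bumps (default c(90, 120)).
#' @param bump_amp Height of each bump on the log-selection scale
#'   (default 2).
#' @return Object of class `true_selection`.
#' @export
true_selection <- function(beta_wind = 0.3, beta_cloud = -0.2,
                           beta_dpressure = 0, beta_rain = 0,
                           sunset_peak = 108, tide_peak = -238,
                           smooth_scales = c(90, 120), bump_amp = 2) {
  if (any(smooth_scales <= 0) || length(smooth_scales) != 2) {
    abort("smooth_scales must be two positive widths",
          class = "knotflight_parameter_error")
  }
  structure(list(beta_wind = beta_wind, beta_cloud = beta_cloud,
                 beta_dpressure = beta_dpressure, beta_rain = beta_rain,
                 sunset_peak = sunset_peak, tide_peak = tide_peak,
                 smooth_scales = smooth_scales, bump_amp = bump_amp),
            class = "true_selection")
}

#' Log-selection surface of a ground-truth selection
#'
#' Evaluates the linear predictor of a [true_selection()] on annotated
#' covariates (the inverse model the generator samples from).
#'
#' @param covariates A tibble from [annotate_times()].
#' @param truth A [true_selection()].
#' @return Numeric log-selection values.
#' @export
selection_eta <- function(covariates, truth) {
  stopifnot(inherits(truth, "true_selection"))
  bump <- function(m, peak, scale) {
    truth$bump_amp * exp(-0.5 * ((m - peak) / scale)^2)
  }
  truth$beta_wind * covariates$wind_assist +
    truth$beta_cloud * covariates$cloud +
    truth$beta_dpressure * covariates$d_pressure +
    truth$beta_rain * covariates$rain +
    bump(covariates$min_to_sunset, truth$sunset_peak, truth$smooth_scales[1]) +
    bump(covariates$min_to_hightide, truth$tide_peak, truth$smooth_scales[2])
}

#' Draw departure times from a known selection function
#'
#' Samples `n` departure times from a 10-min candidate grid with
#' probability proportional to `exp(eta)`, where `eta` is the
#' ground-truth log-selection evaluated on the grid covariates. Draws are
#' independent across birds, so ties are possible.
#'
#' @param env An [env_bundle()] covering the grid.
#' @param truth A [true_selection()].
#' @param n Number of departures.
#' @param grid POSIXct candidate grid (10-min cadence); all covariates
#'   must be defined on it.
#' @param seed Optional integer.
#' @return Sorted POSIXct departure times of length `n`.
#' @export
sim_departure_times <- function(env, truth, n, grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- annotate_times(grid, env) # coverage errors propagate from here
  eta <- selection_eta(cov, truth)
  p <- exp(eta - max(eta))
  sort(grid[sample.int(length(grid), n, replace = TRUE, prob = p)])
}
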