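# Environmental covariates for candidate departure times: wind assistance
# under full drift, hourly pressure change, cloud/rain lookups, and the
# bundle object tying the series together.

#' Wind assistance under full drift
#'
#' The component of the wind vector along the intended track direction:
#' `wind_speed * cos(theta_to - track_bearing)`, where `theta_to` is the
#' direction the wind blows towards (meteorological direction + 180).
#' Positive values are tailwinds. Full drift means no airspeed or heading
#' correction is applied.
#'
#' @param wind_speed m/s, non-negative.
#' @param wind_dir_from Meteorological wind direction in degrees (direction
#'   the wind comes FROM, 0 = north).
#' @param track_bearing Intended track direction, compass degrees.
#' @return Signed assistance in m/s, bounded by `wind_speed` in absolute
#'   value.
#' @examples
#' wind_assistance(10, 90, 270) # +10: easterly wind, westward track
#' @export
wind_assistance <- function(wind_speed, wind_dir_from, track_bearing) {
  if (any(wind_speed < 0)) {
    abort("wind_speed must be non-negative",
          class = "knotflight_parameter_error")
  }
  to <- (wind_dir_from + 180) %% 360
  wind_speed * cos(deg2rad(to - track_bearing))
}

#' Hourly pressure change
#'
#' Pressure at the hour containing `t` minus pressure at the hour
#' containing `t - window`. Hourly records are matched by flooring to the
#' hour; no interpolation.
#'
#' @param weather Hourly tibble with columns `t`, `pressure` (mb).
#' @param t POSIXct timestamps.
#' @param window Hours, default 1.
#' @return Pressure difference in mb.
#' @export
delta_pressure <- function(weather, t, window = 1) {
  t <- as_utc(t)
  p_at <- hourly_lookup(weather, t, "pressure")
  p_before <- hourly_lookup(weather, t - window * 3600, "pressure")
  p_at - p_before
}

# floor-to-hour match against an hourly series; coverage error names the column
hourly_lookup <- function(weather, t, col) {
  if (!all(c("t", col) %in% names(weather))) {
    abort(paste0("weather series must have columns t, ", col),
          class = "knotflight_schema_error")
  }
  key <- floor(as.numeric(t) / 3600)
  wkey <- floor(as.numeric(weather$t) / 3600)
  i <- match(key, wkey)
  if (anyNA(i)) {
    bad <- t[which(is.na(i))[1]]
    abort(paste0("no hourly ", col, " record covering ",
                 format(bad, "%Y-%m-%d %H:%M", tz = "UTC")),
          class = "knotflight_coverage_error")
  }
  weather[[col]][i]
}

# nearest-stamp match against a regular series (10-min cloud, tide)
nearest_lookup <- function(series, t, col, max_gap_min = 10) {
  st <- as.numeric(series$t)
  tt <- as.numeric(t)
  idx <- findInterval(tt, st, all.inside = TRUE)
  idx2 <- pmin(idx + 1L, length(st))
  use_next <- abs(st[idx2] - tt) < abs(st[idx] - tt)
  i <- ifelse(use_next, idx2, idx)
  if (any(abs(st[i] - tt) > max_gap_min * 60)) {
    bad <- t[which(abs(st[i] - tt) > max_gap_min * 60)[1]]
    abort(paste0("no ", col, " record within ", max_gap_min, " min of ",
                 format(as_utc(bad), "%Y-%m-%d %H:%M", tz = "UTC")),
          class = "knotflight_coverage_error")
  }
  series[[col]][i]
}

#' Bundle environmental series for covariate annotation
#'
#' Stores the tidal, cloud and weather series together with the site
#' coordinates, applies the station lag to the tide series, and derives
#' high-tide times.
#'
#' @param tide Tibble `t`, `level` at 10-min cadence (reference station).
#' @param cloud Tibble `t`, `okta` at 10-min cadence (integers 0-8).
#' @param weather Hourly tibble `t`, `pressure`, `rain`, `wind_speed`,
#'   `wind_dir` (direction FROM, degrees).
#' @param site_lat,site_lon Site coordinates for solar computation
#'   (defaults: the Griend area of the Dutch Wadden Sea).
#' @param tide_lag Station lag in minutes added to the tide series
#'   (default 30).
#' @param goal_bearing Default track bearing for wind assistance, compass
#'   degrees (default 262, the Wadden Sea to Wash direction).
#' @return An object of class `env_bundle`.
#' @export
env_bundle <- function(tide, cloud, weather, site_lat = 53.25,
                       site_lon = 5.25, tide_lag = 30, goal_bearing = 262) {
  if (!all(c("t", "okta") %in% names(cloud)) ||
      any(cloud$okta < 0 | cloud$okta > 8)) {
    abort("cloud series needs t, okta with okta in 0..8",
          class = "knotflight_schema_error")
  }
  need <- c("t", "pressure", "rain", "wind_speed", "wind_dir")
  if (!all(need %in% names(weather))) {
    abort(paste0("weather series needs columns ",
                 paste(need, collapse = ", ")),
          class = "knotflight_schema_error")
  }
  tide_lagged <- lag_series(tide, tide_lag)
  structure(list(
    tide = as_tibble(tide_lagged),
    cloud = as_tibble(cloud),
    weather = as_tibble(weather),
    site = c(lat = site_lat, lon = site_lon),
    goal_bearing = goal_bearing,
    high_tides = find_high_tides(tide_lagged)
  ), class = "env_bundle")
}

#' Annotate timestamps with departure covariates
#'
#' Computes, for each timestamp, the six covariates used in the departure
#' resource-selection model: signed minutes to the nearest sunset and to
#' the nearest high tide, cloud cover (okta, nearest 10-min record), rain
#' (0.1 mm/h, hour containing the time), 1-h pressure change (mb), and
#' full-drift wind assistance (m/s) along `track_bearing`. Year is
#' extracted from the timestamp.
#'
#' @param times POSIXct timestamps (UTC) — typically departure times plus
#'   sampled available times.
#' @param env An [env_bundle()].
#' @param track_bearing Compass degrees; defaults to the bundle's goal
#'   bearing.
#' @return A tibble with one row per time: `t`, `min_to_sunset`,
#'   `min_to_hightide`, `cloud`, `rain`, `d_pressure`, `wind_assist`,
#'   `year`.
#' @export
annotate_times <- function(times, env, track_bearing = NULL) {
  stopifnot(inherits(env, "env_bundle"))
  times <- as_utc(times)
  track_bearing <- track_bearing %||% env$goal_bearing
  ws <- hourly_lookup(env$weather, times, "wind_speed")
  wd <- hourly_lookup(env$weather, times, "wind_dir")
  tibble(
    t = times,
    min_to_sunset = minutes_to_sunset(times, env$site["lat"], env$site["lon"]),
    min_to_hightide = time_to_high_tide(times, env$high_tides),
    cloud = nearest_lookup(env$cloud, times, "okta"),
    rain = hourly_lookup(env$weather, times, "rain"),
    d_pressure = delta_pressure(env$weather, times),
    wind_assist = wind_assistance(ws, wd, track_bearing),
    year = as.integer(format(times, "%Y", tz = "UTC"))
  )
}
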