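# Synthetic environmental series: a noisy sinusoidal semidiurnal tide,
# autocorrelated hourly weather, and a bounded-walk okta cloud series.
# Cadences match the field data: 10 min for tide and cloud, 1 h for weather.

check_interval <- function(start, end) {
  start <- as_utc(start); end <- as_utc(end)
  if (end <= start) {
    abort("end must be after start", class = "knotflight_interval_error")
  }
  list(start = start, end = end)
}

#' Simulate a tidal water-level series
#'
#' A cosine of the semidiurnal lunar period plus Gaussian noise, sampled
#' every 10 minutes. Only the high-tide times matter downstream, so a
#' noisy sinusoid stands in for station records.
#'
#' @param start,end Interval (POSIXct or coercible), end after start.
#' @param period Tidal period in minutes (default 745).
#' @param amplitude Metres (default 1).
#' @param noise_sd Metres (default 0.05).
#' @param seed Optional integer for reproducibility.
#' @return Tibble `t`, `level` on a regular 10-min grid covering
#'   `[start, end]`.
#' @export
sim_tide <- function(start, end, period = 745, amplitude = 1,
                     noise_sd = 0.05, seed = NULL) {
  iv <- check_interval(start, end)
  stopifnot(period > 0, amplitude > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(iv$start, iv$end, by = 600)
  mins <- as.numeric(t - iv$start, units = "mins")
  tibble(t = t,
         level = amplitude * cos(2 * pi * mins / period) +
           rnorm(length(t), 0, noise_sd))
}

#' Simulate an hourly weather series
#'
#' Pressure follows an AR(1) around its mean; wind speed an AR(1) around a
#' mean speed truncated at zero; wind direction a circular random walk
#' (degrees FROM which the wind blows); rain is zero-inflated exponential
#' in units of 0.1 mm/h.
#'
#' @param start,end Interval.
#' @param seed Optional integer.
#' @param pressure_mean mb (default 1013).
#' @param pressure_phi,pressure_sd AR(1) coefficient and innovation sd for
#'   pressure (defaults 0.95, 0.8 — slow synoptic drift).
#' @param wind_mean,wind_phi,wind_sd Wind-speed AR(1) settings (defaults
#'   6 m/s, 0.9, 1).
#' @param dir_step_sd Circular-walk step sd in degrees/h (default 20).
#' @param rain_prob Probability an hour is rainy (default 0.15).
#' @param rain_mean Mean rainfall of rainy hours, 0.1 mm/h units
#'   (default 5).
#' @return Hourly tibble `t`, `pressure`, `rain`, `wind_speed`, `wind_dir`.
#' @export
sim_weather <- function(start, end, seed = NULL, pressure_mean = 1013,
                        pressure_phi = 0.95, pressure_sd = 0.8,
                        wind_mean = 6, wind_phi = 0.9, wind_sd = 1,
                        dir_step_sd = 20, rain_prob = 0.15, rain_mean = 5) {
  iv <- check_interval(start, end)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(iv$start, iv$end, by = 3600)
  n <- length(t)
  ar1 <- function(mu, phi, sd) {
    x <- numeric(n)
    x[1] <- mu + if (sd > 0 && abs(phi) < 1) {
      rnorm(1, 0, sd / sqrt(1 - phi^2))
    } else 0
    for (i in seq_len(n - 1)) {
      x[i + 1] <- mu + phi * (x[i] - mu) + rnorm(1, 0, sd)
    }
    x
  }
  tibble(
    t = t,
    pressure = ar1(pressure_mean, pressure_phi, pressure_sd),
    rain = rbinom(n, 1, rain_prob) * stats::rexp(n, 1 / rain_mean),
    wind_speed = pmax(0, ar1(wind_mean, wind_phi, wind_sd)),
    wind_dir = (cumsum(c(runif(1, 0, 360), rnorm(n - 1, 0, dir_step_sd)))) %% 360
  )
}

#' Simulate a cloud-cover series
#'
#' Integer okta (eighths of sky covered, 0-8) on a 10-min grid, evolving
#' as a bounded random walk with steps in {-1, 0, +1}.
#'
#' @param start,end Interval.
#' @param seed Optional integer.
#' @param p_move Probability of a step at each 10-min tick (default 0.3).
#' @return Tibble `t`, `okta`.
#' @export
sim_cloud <- function(start, end, seed = NULL, p_move = 0.3) {
  iv <- check_interval(start, end)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(iv$start, iv$end, by = 600)
  n <- length(t)
  okta <- integer(n)
  okta[1] <- sample(0:8, 1)
  steps <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                  prob = c(p_move / 2, 1 - p_move, p_move / 2))
  for (i in seq_len(n - 1)) {
    okta[i + 1] <- min(8L, max(0L, okta[i] + steps[i + 1]))
  }
  tibble(t = t, okta = okta)
}

#' Simulate a full environmental bundle
#'
#' Convenience wrapper generating tide, cloud and weather over one
#' interval and assembling them with [env_bundle()]. The tide series is
#' generated at the reference station (the bundle applies the station
#' lag).
#'
#' @param start,end Interval.
#' @param seed Integer seed; sub-seeds are derived per series.
#' @param ... Passed on to [env_bundle()] (site coordinates, lag, goal
#'   bearing).
#' @return An `env_bundle`.
#' @export
sim_env <- function(start, end, seed = 1, ...) {
  env_bundle(
    tide = sim_tide(start, end, seed = seed),
    cloud = sim_cloud(start, end, seed = seed + 1L),
    weather = sim_weather(start, end, seed = seed + 2L),
    ...
  )
}
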