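# Solar geometry: sunset times from the standard NOAA equations
# (sun centre at -0.833 degrees altitude, i.e. refraction + half diameter).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# NOAA solar quantities at a given Julian century; all angles in degrees
solar_terms <- function(jc) {
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(deg2rad(M)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(lambda))))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) - 1.25 * e^2 * sin(2 * deg2rad(M))
  )
  list(decl = decl, eqtime = eqtime)
}

#' Sunset time (UTC)
#'
#' Sunset for a calendar date at given coordinates, defined as the moment
#' the sun's centre reaches -0.833 degrees altitude (accounts for standard
#' atmospheric refraction and the solar radius). Accuracy is within about
#' two minutes of almanac values at temperate latitudes.
#'
#' @param date A `Date` (or something coercible); vectorized.
#' @param lat,lon Degrees north / east. `abs(lat)` must be below 66 so a
#'   sunset exists year-round.
#' @return POSIXct sunset times, UTC.
#' @export
sunset_time <- function(date, lat, lon) {
  if (abs(lat) >= 66) {
    abort("no year-round sunset at polar latitudes (|lat| >= 66)",
          class = "knotflight_solar_error")
  }
  date <- as.Date(date)
  one <- function(d) {
    day0 <- as.POSIXct(as.character(d), tz = "UTC")
    # Julian day at 12:00 UTC of d, then one refinement at the sunset estimate
    jd_noon <- as.numeric(day0) / 86400 + 2440587.5 + 0.5
    minutes <- NA_real_
    jc <- (jd_noon - 2451545) / 36525
    for (pass in 1:2) {
      st <- solar_terms(jc)
      cosha <- cos(deg2rad(90.833)) /
        (cos(deg2rad(lat)) * cos(deg2rad(st$decl))) -
        tan(deg2rad(lat)) * tan(deg2rad(st$decl))
      if (abs(cosha) > 1) {
        abort("sun does not set on this date at these coordinates",
              class = "knotflight_solar_error")
      }
      ha <- rad2deg(acos(cosha))
      minutes <- 720 - 4 * lon - st$eqtime + 4 * ha
      jc <- (jd_noon - 0.5 + minutes / 1440 - 2451545) / 36525
    }
    day0 + minutes * 60
  }
  out <- lapply(date, one)
  do.call(c, out)
}

#' Signed minutes from the nearest sunset
#'
#' For each timestamp, minutes relative to the closest sunset at the site:
#' negative before sunset, positive after.
#'
#' @param times POSIXct timestamps (UTC).
#' @param lat,lon Site coordinates, degrees.
#' @return Numeric minutes.
#' @export
minutes_to_sunset <- function(times, lat, lon) {
  times <- as_utc(times)
  dates <- sort(unique(as.Date(times)))
  grid_dates <- sort(unique(c(dates - 1, dates, dates + 1)))
  ss <- as.numeric(sunset_time(grid_dates, lat, lon))
  tt <- as.numeric(times)
  vapply(tt, function(ti) {
    d <- ti - ss
    d[which.min(abs(d))] / 60
  }, numeric(1))
}
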