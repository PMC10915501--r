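# Tidal series handling: station lag, high-tide detection, signed minutes
# to the nearest high tide.

#' Shift a time series forward in time
#'
#' Applies a station lag: every timestamp is moved `lag` minutes later,
#' values untouched. Used to translate a water-level series recorded at a
#' reference station to the study site.
#'
#' @param series Tibble with a `t` column (POSIXct).
#' @param lag Minutes, default 30.
#' @return The lagged tibble.
#' @export
lag_series <- function(series, lag = 30) {
  if (!"t" %in% names(series)) {
    abort("series must have a t column", class = "knotflight_schema_error")
  }
  mutate(series, t = .data$t + lag * 60)
}

#' Detect high tides in a water-level series
#'
#' A timestamp is a high tide if its level is the maximum over a centered
#' +/- 3 h neighbourhood and strictly exceeds at least one neighbour (flat
#' series have no peaks). Peaks closer together than 8 h are merged,
#' keeping the higher one — the semidiurnal tide cannot produce two high
#' waters that close.
#'
#' @param tide Tibble with columns `t` (POSIXct, regular cadence) and
#'   `level` (metres or cm; units irrelevant).
#' @param neighbourhood Half-width of the local-max window, minutes
#'   (default 180).
#' @param min_separation Minimum spacing between successive high tides,
#'   minutes (default 480).
#' @return Sorted POSIXct vector of high-tide times.
#' @export
find_high_tides <- function(tide, neighbourhood = 180, min_separation = 480) {
  if (!all(c("t", "level") %in% names(tide))) {
    abort("tide series must have columns t, level",
          class = "knotflight_schema_error")
  }
  tide <- arrange(tide, .data$t)
  tt <- as.numeric(tide$t)
  lv <- tide$level
  n <- length(tt)
  if (n < 3 || diff(range(lv)) == 0) {
    abort("no tidal peaks found (series flat or too short)",
          class = "knotflight_tide_error")
  }
  half <- neighbourhood * 60
  # interior points only: an endpoint that the series rises into is a
  # truncated, unobservable peak, not a high tide
  is_peak <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    win <- which(tt >= tt[i] - half & tt <= tt[i] + half)
    lv[i] >= max(lv[win]) &&
      (lv[i] > lv[i - 1] || lv[i] > lv[i + 1])
  }, logical(1))
  cand <- which(is_peak)
  if (!length(cand)) {
    abort("no tidal peaks found", class = "knotflight_tide_error")
  }
  # merge candidates within min_separation, keep the higher level
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && tt[i] - tt[keep[length(keep)]] < min_separation * 60) {
      if (lv[i] > lv[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  tide$t[keep]
}

#' Signed minutes from the nearest high tide
#'
#' Negative before high tide, positive after. A timestamp exactly midway
#' between two high tides resolves to the later one (negative sign).
#'
#' @param times POSIXct timestamps.
#' @param high_tides Sorted POSIXct high-tide times (see
#'   [find_high_tides()]).
#' @param period Tidal period in minutes, used only for the coverage check
#'   at the series ends (default 745, the semidiurnal lunar period).
#' @return Numeric minutes.
#' @export
time_to_high_tide <- function(times, high_tides, period = 745) {
  times <- as_utc(times)
  ht <- sort(as.numeric(as_utc(high_tides)))
  if (!length(ht)) {
    abort("empty high-tide list", class = "knotflight_tide_error")
  }
  tt <- as.numeric(times)
  lo <- ht[1] - period * 60 / 2
  hi <- ht[length(ht)] + period * 60 / 2
  if (any(tt < lo - 1e-6 | tt > hi + 1e-6)) {
    abort("timestamp outside high-tide coverage",
          class = "knotflight_coverage_error")
  }
  vapply(tt, function(ti) {
    d <- ti - ht
    i <- which(abs(d) == min(abs(d)))
    # tie (exact midpoint): take the later tide, i.e. the negative offset
    d[i[length(i)]] / 60
  }, numeric(1))
}
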