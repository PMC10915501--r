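# Shared fixture builders: everything is generated in code at test time.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# straight-line track builder: cadence in seconds, speed m/s along a bearing
make_track <- function(n, t0 = utc("2019-09-05 12:00:00"), cadence = 10,
                       x0 = 0, y0 = 0, speed = 18, bearing_deg = 262,
                       sd = 10, tag = "tagA") {
  tt <- t0 + cadence * (seq_len(n) - 1)
  step <- speed * cadence
  b <- bearing_deg * pi / 180
  tibble::tibble(
    tag_id = tag, t = tt,
    x = x0 + step * sin(b) * (seq_len(n) - 1),
    y = y0 + step * cos(b) * (seq_len(n) - 1),
    sd = sd
  )
}

# small environmental bundle used by annotation and RSF tests
small_env <- function(seed = 1, start = utc("2019-09-01"),
                      end = utc("2019-10-15")) {
  sim_env(start - 5 * 86400, end + 86400, seed = seed)
}

# independent straightness oracle: plain loops, no shared code with the
# package's vectorized implementation
brute_straightness <- function(track, window = 20, max_turn = 90) {
  track <- track[order(track$t), ]
  tmax <- max(as.numeric(track$t))
  w <- track[as.numeric(track$t) >= tmax - window * 60, ]
  if (nrow(w) < 3) return(NA)
  bearings <- c()
  for (i in seq_len(nrow(w) - 1)) {
    dx <- w$x[i + 1] - w$x[i]
    dy <- w$y[i + 1] - w$y[i]
    if (dx == 0 && dy == 0) next
    bearings <- c(bearings, (atan2(dx, dy) * 180 / pi) %% 360)
  }
  if (length(bearings) < 2) return(TRUE)
  for (i in seq_len(length(bearings) - 1)) {
    d <- abs(bearings[i + 1] - bearings[i]) %% 360
    if (min(d, 360 - d) >= max_turn) return(FALSE)
  }
  TRUE
}

# departure events tibble from simulated departure times
events_from_times <- function(times) {
  tibble::tibble(tag_id = sprintf("b%03d", seq_along(times)),
                 departure_time = times)
}
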