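# Tidal alignment, sunset, wind assistance, pressure change, and the
# covariate annotation round trip.

test_that("series lag shifts timestamps and is additive", {
  tide <- sim_tide(utc("2019-09-01"), utc("2019-09-02"), noise_sd = 0, seed = 1)
  expect_equal(lag_series(tide, 0)$t, tide$t)
  expect_equal(lag_series(tide, 30)$t, tide$t + 1800)
  expect_equal(lag_series(lag_series(tide, 30), 30)$t,
               lag_series(tide, 60)$t)
})

test_that("high tides of a noise-free cosine sit at multiples of the period", {
  t0 <- utc("2019-09-01")
  tide <- sim_tide(t0, t0 + 4 * 86400, period = 745, amplitude = 1,
                   noise_sd = 0)
  ht <- find_high_tides(tide)
  mins <- as.numeric(ht - t0, units = "mins")
  # analytic maxima at 0, 745, 1490, ... within the 10-min grid
  expect_true(all(abs(mins - round(mins / 745) * 745) <= 10))
  expect_gte(length(ht), 7)
  expect_true(all(diff(as.numeric(ht)) >= 8 * 3600))

  # small noise moves detected peaks only slightly
  tide_n <- sim_tide(t0, t0 + 4 * 86400, period = 745, amplitude = 1,
                     noise_sd = 0.01, seed = 4)
  ht_n <- find_high_tides(tide_n)
  mins_n <- as.numeric(ht_n - t0, units = "mins")
  expect_true(all(abs(mins_n - round(mins_n / 745) * 745) <= 20))

  flat <- tide
  flat$level <- 1
  expect_error(find_high_tides(flat), class = "knotflight_tide_error")
})

test_that("time to high tide is signed minutes to the closest peak", {
  ht <- utc(c("2019-09-05 00:00:00", "2019-09-05 12:25:00"))
  expect_equal(time_to_high_tide(ht[1], ht), 0)
  expect_equal(time_to_high_tide(utc("2019-09-05 04:00:00"), ht), 240)
  expect_equal(time_to_high_tide(utc("2019-09-05 10:00:00"), ht), -145)
  expect_error(time_to_high_tide(utc("2019-09-08 00:00:00"), ht),
               class = "knotflight_coverage_error")
})

test_that("sunset matches an independent almanac within 2 minutes", {
  dates <- as.Date(c("2019-01-15", "2019-02-15", "2019-03-20", "2019-04-15",
                     "2019-05-15", "2019-06-21", "2019-07-15", "2019-08-15",
                     "2019-09-23", "2019-10-15", "2019-11-15", "2019-12-21"))
  # minutes after 00:00 UTC at 53.25 N, 5.25 E, from an independently coded
  # solar algorithm (Julian-cycle sunrise equation)
  almanac <- c(949.91, 1008.44, 1070.58, 1117.34, 1170.46, 1210.17,
               1199.76, 1148.83, 1057.50, 1004.93, 944.40, 922.29)
  got <- as.numeric(sunset_time(dates, 53.25, 5.25) -
                      as.POSIXct(as.character(dates), tz = "UTC"),
                    units = "mins")
  expect_true(all(abs(got - almanac) < 2))

  # equinox: sunset near 18:00 UTC at lon 0 (the equation of time and the
  # -0.833 degree depression together shift it ~13 min late), and 1 h
  # earlier in UTC at 15 E
  eq <- sunset_time(as.Date("2019-03-20"), 53, 0)
  expect_lt(abs(as.numeric(eq - utc("2019-03-20 18:00:00"),
                           units = "mins")), 15)
  eq15 <- sunset_time(as.Date("2019-03-20"), 53, 15)
  expect_lt(abs(as.numeric(eq - eq15, units = "mins") - 60), 5)

  expect_error(sunset_time(as.Date("2019-06-21"), 70, 0),
               class = "knotflight_solar_error")
})

test_that("wind assistance closed forms, bound and rotational invariance", {
  expect_equal(wind_assistance(10, 90, 270), 10)   # pure tailwind
  expect_equal(wind_assistance(10, 270, 270), -10) # pure headwind
  expect_equal(wind_assistance(8, 0, 270), 0, tolerance = 1e-12) # crosswind
  set.seed(12)
  for (i in 1:50) {
    s <- runif(1, 0, 25)
    d <- runif(1, 0, 360)
    b <- runif(1, 0, 360)
    phi <- runif(1, -360, 360)
    a <- wind_assistance(s, d, b)
    expect_lte(abs(a), s + 1e-12)
    expect_equal(wind_assistance(s, (d + phi) %% 360, (b + phi) %% 360), a,
                 tolerance = 1e-9)
  }
  # |A| attains the wind speed only when wind axis is parallel to track
  expect_equal(abs(wind_assistance(7, 33, (33 + 180) %% 360)), 7)
})

test_that("pressure change uses floor-to-hour differences", {
  w <- tibble::tibble(
    t = utc("2019-09-05 00:00:00") + 3600 * (0:23),
    pressure = 1010, rain = 0, wind_speed = 5, wind_dir = 90
  )
  expect_equal(delta_pressure(w, utc("2019-09-05 10:20:00")), 0)
  w2 <- w
  w2$pressure <- 1000 + 2 * (0:23) # +2 mb/h ramp
  expect_equal(delta_pressure(w2, utc("2019-09-05 10:20:00")), 2)
  expect_equal(delta_pressure(w2, utc("2019-09-05 10:59:00")), 2)
  w3 <- w
  w3$pressure[w3$t == utc("2019-09-05 17:00:00")] <- 1010
  w3$pressure[w3$t == utc("2019-09-05 18:00:00")] <- 1013
  w3$pressure[w3$t == utc("2019-09-05 17:00:00")] <- 1010
  expect_equal(delta_pressure(w3, utc("2019-09-05 18:20:00")), 3)
  expect_error(delta_pressure(w, utc("2019-09-07 00:00:00")),
               class = "knotflight_coverage_error")
})

test_that("annotation matches series values at their own stamps", {
  env <- small_env(seed = 2)
  t <- utc("2019-09-10 17:30:00") # exactly a 10-min cloud stamp
  row <- annotate_times(t, env)
  expect_equal(row$cloud, env$cloud$okta[env$cloud$t == t])
  hr <- utc("2019-09-10 17:00:00")
  expect_equal(row$rain, env$weather$rain[env$weather$t == hr])
  ws <- env$weather$wind_speed[env$weather$t == hr]
  wd <- env$weather$wind_dir[env$weather$t == hr]
  expect_equal(row$wind_assist, wind_assistance(ws, wd, env$goal_bearing))
  expect_equal(row$year, 2019L)
  expect_true(abs(row$min_to_hightide) <= 745 / 2 + 10)
})

test_that("annotating sampled departure times reproduces generator covariates", {
  env <- small_env(seed = 3)
  truth <- true_selection()
  grid <- seq(utc("2019-09-05"), utc("2019-10-05"), by = 600)
  dep <- sim_departure_times(env, truth, 30, grid, seed = 9)
  cov_direct <- annotate_times(dep, env)
  # the generator sampled from exp(eta) on the same covariates: recomputing
  # eta from the annotation must match the generator's own surface
  cov_grid <- annotate_times(grid, env)
  eta_grid <- selection_eta(cov_grid, truth)
  idx <- match(as.numeric(dep), as.numeric(grid))
  expect_false(anyNA(idx))
  expect_equal(selection_eta(cov_direct, truth), eta_grid[idx])
})
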