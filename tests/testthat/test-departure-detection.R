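# Bearings, the four departure criteria, pass-through exclusion, the
# classifier against generator labels, and the cut-off accounting.

test_that("compass bearings and angular differences", {
  expect_equal(bearing(0, 0, 0, 1), 0)
  expect_equal(bearing(0, 0, -1, 0), 270)
  expect_equal(bearing(0, 0, 1, 1), 45)
  expect_error(bearing(1, 1, 1, 1), class = "knotflight_geometry_error")

  expect_equal(angular_difference(350, 10), 20)
  expect_equal(angular_difference(90, 270), 180)
  expect_equal(angular_difference(100, 30), 70)
})

test_that("detection-gap criterion is strict at 2 h", {
  tr <- make_track(5, t0 = utc("2019-09-05 11:20:00"), cadence = 600)
  # last fix 12:00; detection at 13:30 is within 2 h
  det <- tibble::tibble(tag_id = "tagA", t = utc("2019-09-05 13:30:00"))
  expect_true(criterion_detection_gap(tr, det))
  # detection at 14:01 is more than 2 h after the last fix
  det$t <- utc("2019-09-05 14:01:00")
  expect_false(criterion_detection_gap(tr, det))
  # exactly at the bound passes (strictly 'more than')
  det$t <- utc("2019-09-05 14:00:00")
  expect_true(criterion_detection_gap(tr, det))
  expect_true(criterion_detection_gap(tr, det[0, ]))
})

test_that("outside-core criterion treats the boundary as inside", {
  rg <- default_regions()
  tr <- make_track(3, speed = 0, x0 = 0, y0 = 0)
  expect_false(criterion_outside_core(tr, rg)) # centroid
  tr2 <- make_track(3, speed = 0, x0 = -14000, y0 = 0)
  expect_true(criterion_outside_core(tr2, rg))
  tr3 <- make_track(3, speed = 0, x0 = 4000, y0 = 0) # exactly on boundary
  expect_false(criterion_outside_core(tr3, rg))
})

test_that("straightness criterion is strict below 90 degrees", {
  tr <- make_track(30, cadence = 60)
  expect_true(criterion_straightness(tr))

  # right-angle dogleg inside the final window: one turn of exactly 90
  dog <- tibble::tibble(
    tag_id = "d", t = utc("2019-09-05 12:00:00") + 60 * (0:10),
    x = c(0:5 * 100, rep(500, 5)),
    y = c(rep(0, 6), 1:5 * 100), sd = 10
  )
  expect_false(criterion_straightness(dog))

  # zigzag with turns 30, 89, 45: all strictly below 90
  b <- c(0, 30, -59, -14) # successive bearings differing by 30, 89, 45
  x <- cumsum(c(0, sin(b * pi / 180) * 100))
  y <- cumsum(c(0, cos(b * pi / 180) * 100))
  zig <- tibble::tibble(tag_id = "z", t = utc("2019-09-05 12:00:00") + 60 * (0:4),
                        x = x, y = y, sd = 10)
  expect_true(criterion_straightness(zig))

  # fewer than 3 fixes in the window: insufficient data, not FALSE
  expect_true(is.na(criterion_straightness(make_track(2, cadence = 60))))
})

test_that("straightness agrees with a brute-force oracle on random windows", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:9, 1)
    tr <- tibble::tibble(
      tag_id = "r", t = utc("2019-09-05 12:00:00") + 120 * (seq_len(n) - 1),
      x = cumsum(rnorm(n, 0, 200)), y = cumsum(rnorm(n, 0, 200)), sd = 10
    )
    expect_identical(criterion_straightness(tr), brute_straightness(tr))
  }
})

test_that("westward-over-sea criterion and its inclusive bearing interval", {
  rg <- default_regions()
  tr <- make_track(30, cadence = 60, speed = 18, bearing_deg = 270,
                   x0 = -9000, y0 = 0)
  expect_true(criterion_westward_over_sea(tr, rg))
  east <- make_track(30, cadence = 60, speed = 18, bearing_deg = 90,
                     x0 = -42000, y0 = 0)
  expect_false(criterion_westward_over_sea(east, rg)) # eastward
  edge <- make_track(30, cadence = 60, speed = 18, bearing_deg = 225,
                     x0 = -9000, y0 = 20000)
  expect_true(criterion_westward_over_sea(edge, rg)) # 225 inclusive
})

test_that("pass-through exclusion needs an outside start at transit speed", {
  rg <- default_regions()
  inside <- make_track(10, cadence = 60, x0 = 0, y0 = 0, speed = 18)
  expect_false(exclude_passthrough(inside, rg))
  entering <- make_track(10, cadence = 60, x0 = 5200, y0 = 0,
                         bearing_deg = 262, speed = 18)
  expect_true(exclude_passthrough(entering, rg))
  loiter <- make_track(10, cadence = 60, x0 = 5200, y0 = 0, speed = 0.5)
  expect_false(exclude_passthrough(loiter, rg))
})

test_that("classifier recovers generator labels exactly on noise-free tracks", {
  scen <- sim_scenario(n_resident = 6, n_departing = 4, n_passthrough = 2,
                       start = "2019-09-01", end = "2019-09-06",
                       fix_interval = 120, loc_error_sd = 0, seed = 21)
  sim <- sim_tracks(scen)
  cls <- classify_departures(preprocess_tracks(sim$tracks),
                             sim$detections, default_regions())
  merged <- merge(cls, sim$labels, by = "tag_id")
  expect_equal(nrow(merged), 12)
  # confusion matrix is diagonal
  expect_true(all(merged$departed[merged$class == "departing"]))
  expect_false(any(merged$departed[merged$class != "departing"]))
  expect_true(all(merged$reason[merged$class == "passthrough"] == "pass_through"))
  expect_true(all(merged$reason[merged$class == "resident"] == "last_fix_in_core"))
  # departure times recovered close to the true take-off instants
  dep <- merged[merged$class == "departing", ]
  dt_min <- abs(as.numeric(dep$departure_time.x) -
                  as.numeric(dep$departure_time.y)) / 60
  expect_true(all(dt_min <= 10))
})

test_that("a false departure (detections continue 3 h on) is rejected", {
  scen <- sim_scenario(n_resident = 0, n_departing = 1, n_passthrough = 0,
                       start = "2019-09-01", end = "2019-09-06",
                       fix_interval = 120, loc_error_sd = 0, seed = 5)
  sim <- sim_tracks(scen)
  tr <- preprocess_tracks(sim$tracks)
  # fixture: the tag keeps being detected for 3 h after its last fix
  late <- tibble::tibble(tag_id = tr$tag_id[1],
                         t = max(tr$t) + 3600 * (1:3))
  det <- rbind(sim$detections, late)
  cls <- classify_departure(tr, det, default_regions())
  expect_false(cls$departed)
  expect_equal(cls$reason, "detections_continue")
})

test_that("classifier recall stays high under 50 m localization noise", {
  scen <- sim_scenario(n_resident = 2, n_departing = 30, n_passthrough = 0,
                       start = "2019-09-01", end = "2019-09-06",
                       fix_interval = 120, loc_error_sd = 50, seed = 77)
  sim <- sim_tracks(scen)
  cls <- classify_departures(preprocess_tracks(sim$tracks),
                             sim$detections, default_regions())
  merged <- merge(cls, sim$labels, by = "tag_id")
  recall <- mean(merged$departed[merged$class == "departing"])
  expect_gte(recall, 0.95)
})

test_that("cut-off date is the inverse empirical CDF and monotone in q", {
  d0 <- as.Date("2019-11-06")
  expect_equal(cutoff_date(rep(d0, 20)), d0)
  days <- as.Date("2019-08-01") + 0:99 # days 1..100
  expect_equal(cutoff_date(days, 0.95), as.Date("2019-08-01") + 94)
  expect_equal(cutoff_date(d0), d0) # single departure
  expect_error(cutoff_date(as.Date(character(0))),
               class = "knotflight_nodata_error")
  set.seed(8)
  dd <- as.Date("2019-09-01") + sample(0:60, 40, replace = TRUE)
  qs <- c(0.2, 0.5, 0.8, 0.95, 1)
  cds <- as.numeric(vapply(qs, function(q) cutoff_date(dd, q), numeric(1)))
  expect_true(all(diff(cds) >= 0))
})

test_that("departure proportions reproduce the season percentages", {
  cut <- as.Date("2019-11-06")
  p <- departure_proportions(rep(cut - 5, 34), rep(cut + 10, 58), cut)
  expect_equal(p$pct_departed, 37.0)
  expect_equal(p$n_departed + p$n_remaining, 92)
  p2 <- departure_proportions(rep(cut - 5, 27), rep(cut + 10, 47), cut)
  expect_equal(p2$pct_departed, 36.5)
  p3 <- departure_proportions(as.Date(character(0)), rep(cut + 1, 10), cut)
  expect_equal(p3$pct_departed, 0)
  expect_error(
    departure_proportions(rep(cut + 5, 3), rep(cut - 20, 4), cut),
    class = "knotflight_nodata_error"
  )
})
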