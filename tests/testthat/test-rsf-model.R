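# Used/available design shape, the weighted GAM, selection curves, peaks,
# bootstrap, and the availability-size sensitivity.

test_that("available times fall strictly inside the preceding window", {
  t_used <- utc("2019-09-20 18:30:00")
  set.seed(1)
  av <- sample_available(t_used, n = 30)
  expect_length(av, 30)
  expect_true(all(av < t_used))
  expect_true(all(av >= t_used - 96 * 3600))
  expect_equal(length(unique(av)), 30)

  # n equal to the full 10-min grid returns the whole grid
  all576 <- sample_available(t_used, n = 576)
  expect_length(all576, 576)
  expect_equal(min(all576), t_used - 96 * 3600)
  expect_error(sample_available(t_used, n = 577),
               class = "knotflight_sampling_error")

  set.seed(7)
  a <- sample_available(t_used, 30)
  set.seed(7)
  b <- sample_available(t_used, 30)
  expect_identical(a, b)
})

test_that("design has one used and n available rows per event", {
  env <- small_env(seed = 5)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 40, grid, seed = 2)
  d <- build_rsf_design(events_from_times(dep), env, seed = 3)
  expect_equal(nrow(d), 40 + 1200)
  expect_equal(sum(d$response), 40)
  expect_equal(sum(d$response == 0), 1200) # 40 events x 30 available
  expect_equal(sum(d$weight), 40 * 1 + 1200 * 1000)
  expect_true(all(table(d$event_id) == 31))

  d1 <- build_rsf_design(events_from_times(dep[1]), env, n_avail = 1,
                         seed = 4)
  expect_equal(nrow(d1), 2)
})

test_that("unpenalized linear fit matches a weighted logistic oracle", {
  env <- small_env(seed = 8)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 120, grid, seed = 5)
  d <- build_rsf_design(events_from_times(dep), env, seed = 6)
  lin <- c("wind_assist", "cloud", "d_pressure", "rain",
           "min_to_sunset", "min_to_hightide")
  f <- suppressMessages(fit_rsf(d, linear = lin, smooth = character(0)))
  oracle <- glm(
    response ~ wind_assist + cloud + d_pressure + rain +
      min_to_sunset + min_to_hightide,
    family = binomial(), data = d, weights = d$weight
  )
  expect_lt(max(abs(coef(f$gam) - coef(oracle))), 1e-4)
})

test_that("estimates are insensitive to scaling the available weights", {
  env <- small_env(seed = 9)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 100, grid, seed = 7)
  ev <- events_from_times(dep)
  d1 <- build_rsf_design(ev, env, avail_weight = 1000, seed = 8)
  d4 <- d1
  d4$weight[d4$response == 0] <- 4000
  f1 <- suppressMessages(fit_rsf(d1))
  f4 <- suppressMessages(fit_rsf(d4))
  t1 <- tidy(f1)
  t4 <- tidy(f4)
  slopes <- t1$term != "(Intercept)"
  rel <- abs(t4$estimate[slopes] - t1$estimate[slopes]) /
    pmax(abs(t1$estimate[slopes]), 1e-6)
  expect_true(all(rel < 0.01))
})

test_that("selection curves are scaled to [0, 1] and follow the sign", {
  env <- small_env(seed = 10)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 150, grid, seed = 9)
  f <- suppressMessages(fit_rsf(build_rsf_design(events_from_times(dep),
                                                 env, seed = 10)))
  for (v in c("wind_assist", "min_to_sunset", "min_to_hightide")) {
    cv <- rsf_curve(f, v)
    expect_equal(min(cv$rsf), 0)
    expect_equal(max(cv$rsf), 1)
  }
  # positive wind coefficient: strictly increasing linear curve
  cw <- rsf_curve(f, "wind_assist")
  expect_gt(tidy(f)$estimate[tidy(f)$term == "wind_assist"], 0)
  expect_true(all(diff(cw$rsf) > 0))
  expect_error(rsf_curve(f, "no_such"), class = "knotflight_parameter_error")

  # tidy / glance / autoplot surfaces
  td <- tidy(f, type = "smooth")
  expect_setequal(td$term, c("s(min_to_sunset)", "s(min_to_hightide)"))
  g <- glance(f)
  expect_equal(g$n_events, 150)
  expect_true(g$converged)
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
})

test_that("bootstrap peaks bracket the point estimate and B=1 degenerates", {
  env <- small_env(seed = 11)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 60, grid, seed = 11)
  ev <- events_from_times(dep)
  bp <- suppressMessages(bootstrap_peaks(ev, env, B = 12, seed = 12))
  expect_equal(nrow(bp), 2)
  expect_true(all(bp$ci_lower <= bp$mean_peak & bp$mean_peak <= bp$ci_upper))

  b1 <- suppressMessages(bootstrap_peaks(ev, env, B = 1, seed = 13))
  expect_equal(b1$ci_lower, b1$ci_upper)
  expect_equal(b1$ci_lower, b1$mean_peak)

  expect_error(bootstrap_peaks(ev[1:5, ], env, B = 2),
               class = "knotflight_design_error")
})

test_that("sensitivity analysis is deterministic per size and tabulates", {
  env <- small_env(seed = 13)
  grid <- seq(utc("2019-09-05"), utc("2019-10-10"), by = 600)
  dep <- sim_departure_times(env, true_selection(), 60, grid, seed = 14)
  ev <- events_from_times(dep)
  tab <- suppressMessages(
    sensitivity_n_available(ev, env, candidate_ns = c(30, 30), seed = 21)
  )
  a <- tab[tab$n_avail == 30, ]
  halves <- split(a$estimate, rep(1:2, each = nrow(a) / 2))
  expect_equal(halves[[1]], halves[[2]])

  one <- suppressMessages(
    sensitivity_n_available(ev, env, candidate_ns = 10, seed = 22)
  )
  expect_true(all(one$n_avail == 10))
  expect_true(all(is.na(one$stable)))
})
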