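# End-to-end driver: simulate -> preprocess -> classify -> annotate ->
# fit -> report, fully deterministic for a given configuration.

#' Run the full departure-selection pipeline on a simulated season
#'
#' Generates a synthetic season (tracks, detections, environment) from
#' the configuration, cleans the tracks, classifies departures, builds
#' the used/available design and fits the resource-selection GAM, and
#' assembles a run report whose counts reconcile across stages. With
#' `out_dir` set, all intermediate artifacts are written (CSV/GeoJSON)
#' along with a JSON report.
#'
#' @param config A [pipeline_config()].
#' @param truth A [true_selection()] used to draw departure times
#'   (default [true_selection()]).
#' @param regions A [region_set()] (default [default_regions()]).
#' @param fit_gam Fit the RSF stage? Needs a handful of departures;
#'   default TRUE when at least 5 departures are classified.
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         truth = true_selection(),
                         regions = default_regions(),
                         fit_gam = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  start <- as_utc(config$start)
  end <- as_utc(config$end)

  # environment must cover the availability window before early departures
  env <- sim_env(start - (config$avail_window + 24) * 3600, end + 86400,
                 seed = config$seed, site_lat = config$site_lat,
                 site_lon = config$site_lon, tide_lag = config$tide_lag,
                 goal_bearing = config$goal_bearing)

  grid <- seq(start + 86400, end - 43200, by = 600)
  dep_times <- if (config$n_departing > 0) {
    sim_departure_times(env, truth, config$n_departing, grid)
  } else {
    NULL
  }
  scen <- sim_scenario(
    n_resident = config$n_resident, n_departing = config$n_departing,
    n_passthrough = config$n_passthrough, start = start, end = end,
    fix_interval = config$fix_interval, loc_error_sd = config$loc_error_sd,
    site_lat = config$site_lat, site_lon = config$site_lon,
    seed = config$seed
  )
  sim <- sim_tracks(scen, regions, departure_times = dep_times)

  clean <- preprocess_tracks(sim$tracks,
                             speed_threshold = config$speed_threshold,
                             sd_threshold = config$sd_threshold,
                             smooth_window = config$smooth_window)
  stage_report <- attr(clean, "stage_report")

  cls <- classify_departures(clean, sim$detections, regions,
                             gap = config$gap_hours,
                             window = config$straightness_window,
                             max_turn = config$max_turn,
                             transit_speed = config$transit_speed)
  events <- filter(cls, .data$departed)

  cutoff <- if (nrow(events)) {
    cutoff_date(as.Date(events$departure_time), config$cutoff_q)
  } else {
    as.Date(NA)
  }
  props <- if (nrow(events)) {
    non_dep <- filter(cls, !.data$departed)
    last_active <- sim$detections %>%
      filter(.data$tag_id %in% non_dep$tag_id) %>%
      group_by(.data$tag_id) %>%
      summarise(last = as.Date(max(.data$t)), .groups = "drop")
    departure_proportions(as.Date(events$departure_time),
                          last_active$last, cutoff)
  } else {
    NULL
  }

  do_fit <- fit_gam %||% (nrow(events) >= 5)
  fit <- coefs <- peaks <- NULL
  if (do_fit) {
    design <- build_rsf_design(events, env, n_avail = config$n_avail,
                               window = config$avail_window,
                               avail_weight = config$avail_weight)
    fit <- fit_rsf(design)
    coefs <- tidy(fit)
    peaks <- tibble(
      smooth = fit$smooth,
      peak = vapply(fit$smooth,
                    function(s) suppressWarnings(peak_estimate(fit, s)),
                    numeric(1))
    )
  }

  n_tags <- length(unique(sim$tracks$tag_id))
  report <- structure(list(
    config = config,
    n_tags = n_tags,
    n_fixes_raw = nrow(sim$tracks),
    n_fixes_clean = nrow(clean),
    stage_report = stage_report,
    classifications = cls,
    labels = sim$labels,
    n_departed = nrow(events),
    departures_per_year = events %>%
      mutate(year = as.integer(format(.data$departure_time, "%Y"))) %>%
      dplyr::count(.data$year, name = "n_departures"),
    cutoff_date = cutoff,
    proportions = props,
    coefficients = coefs,
    smooth_peaks = peaks,
    fit = fit
  ), class = "run_report")

  # reconciliation: every raw fix is either retained or removed by a stage
  if (report$n_fixes_raw !=
      report$n_fixes_clean + sum(stage_report$n_removed)) {
    abort("stage counts do not reconcile", class = "knotflight_report_error")
  }
  if (n_tags != nrow(cls)) {
    abort("classification rows do not cover all tags",
          class = "knotflight_report_error")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_localizations(sim$tracks, file.path(out_dir, "localizations.csv"))
    write_detections(sim$detections, file.path(out_dir, "detections.csv"))
    write_tide(env$tide, file.path(out_dir, "tide.csv"))
    write_cloud(env$cloud, file.path(out_dir, "cloud.csv"))
    write_weather(env$weather, file.path(out_dir, "weather.csv"))
    write_regions(regions, file.path(out_dir, "regions.geojson"))
    write_config(config, file.path(out_dir, "config.yaml"))
    readr::write_csv(cls, file.path(out_dir, "classifications.csv"))
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_json <- function(report) {
  list(
    n_tags = report$n_tags,
    n_fixes_raw = report$n_fixes_raw,
    n_fixes_clean = report$n_fixes_clean,
    stage_report = report$stage_report,
    n_departed = report$n_departed,
    departures_per_year = report$departures_per_year,
    cutoff_date = as.character(report$cutoff_date),
    proportions = report$proportions,
    coefficients = report$coefficients,
    smooth_peaks = report$smooth_peaks
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Departure pipeline run\n")
  cat(sprintf(" tags: %d  fixes: %d raw -> %d clean\n",
              x$n_tags, x$n_fixes_raw, x$n_fixes_clean))
  for (i in seq_len(nrow(x$stage_report))) {
    cat(sprintf("  %s removed %d of %d\n", x$stage_report$stage[i],
                x$stage_report$n_removed[i], x$stage_report$n_in[i]))
  }
  cat(sprintf(" departures: %d  cut-off (q=%.2f): %s\n", x$n_departed,
              x$config$cutoff_q, format(x$cutoff_date)))
  if (!is.null(x$proportions)) {
    cat(sprintf(" at cut-off: %d departed vs %d remaining (%.1f%% departed)\n",
                x$proportions$n_departed, x$proportions$n_remaining,
                x$proportions$pct_departed))
  }
  if (!is.null(x$coefficients)) {
    cat(" RSF linear coefficients:\n")
    print(x$coefficients, n = Inf)
    cat(" smooth peaks (min):\n")
    print(x$smooth_peaks, n = Inf)
  }
  invisible(x)
}
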