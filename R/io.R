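# CSV dialects for localizations, detections and environmental series,
# GeoJSON for the region polygons, YAML for the pipeline configuration.
# Timestamps are serialized as ISO-8601 UTC; epoch seconds are accepted
# on input.

iso_utc <- function(t) format(as_utc(t), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time_col <- function(x) {
  if (is.numeric(x)) return(as_utc(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(as_utc(num))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = fmt)
  }
  # epoch-second rows mixed into a character column
  miss <- is.na(out)
  if (any(miss)) out[miss] <- as_utc(suppressWarnings(as.numeric(x[miss])))
  out
}

require_cols <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0(what, " file lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "knotflight_schema_error")
  }
}

#' Write / read localization CSV
#'
#' Columns `tag_id`, `time` (ISO-8601 UTC on write; epoch seconds also
#' accepted on read), `x`, `y`, `sd`, optionally `n_receivers`. On read,
#' malformed rows are dropped with a message, tracks are sorted by tag
#' and time, and duplicate timestamps within a tag keep the lower-sd
#' record.
#'
#' @param tracks Localization tibble.
#' @param path File path.
#' @return `read_localizations` returns the tibble; `write_localizations`
#'   returns `path` invisibly.
#' @export
write_localizations <- function(tracks, path) {
  check_track_cols(tracks, c("tag_id", "t", "x", "y", "sd"))
  out <- tibble(tag_id = tracks$tag_id, time = iso_utc(tracks$t),
                x = tracks$x, y = tracks$y, sd = tracks$sd)
  if ("n_receivers" %in% names(tracks)) out$n_receivers <- tracks$n_receivers
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  require_cols(raw, c("tag_id", "time", "x", "y", "sd"), "localization")
  out <- tibble(
    tag_id = raw$tag_id,
    t = parse_time_col(raw$time),
    x = suppressWarnings(as.numeric(raw$x)),
    y = suppressWarnings(as.numeric(raw$y)),
    sd = suppressWarnings(as.numeric(raw$sd))
  )
  if ("n_receivers" %in% names(raw)) {
    out$n_receivers <- suppressWarnings(as.integer(raw$n_receivers))
  }
  bad <- is.na(out$t) | is.na(out$x) | is.na(out$y) | is.na(out$tag_id)
  if (any(bad)) {
    inform(paste0("skipped ", sum(bad), " malformed localization row(s)"))
    out <- out[!bad, , drop = FALSE]
  }
  out %>%
    arrange(.data$tag_id, .data$t, .data$sd) %>%
    distinct(.data$tag_id, .data$t, .keep_all = TRUE)
}

#' Write / read detection CSV
#'
#' Columns `tag_id`, `time`.
#'
#' @param detections Tibble `tag_id`, `t`.
#' @param path File path.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(tibble(tag_id = detections$tag_id,
                          time = iso_utc(detections$t)), path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  require_cols(raw, c("tag_id", "time"), "detection")
  tibble(tag_id = raw$tag_id, t = parse_time_col(raw$time)) %>%
    arrange(.data$tag_id, .data$t)
}

#' Write / read environmental series CSVs
#'
#' Tide: `timestamp`, `level_cm`. Cloud: `timestamp`, `okta`. Weather:
#' `timestamp`, `pressure_mb`, `rain`, `wind_speed_ms`, `wind_dir_deg`
#' (rain in 0.1 mm/h; wind direction meteorological, degrees FROM).
#'
#' @param tide,cloud,weather The respective tibbles (internal column
#'   names; see [env_bundle()]).
#' @param path File path.
#' @export
write_tide <- function(tide, path) {
  readr::write_csv(tibble(timestamp = iso_utc(tide$t),
                          level_cm = tide$level * 100), path)
  invisible(path)
}

#' @rdname write_tide
#' @export
read_tide <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(raw, c("timestamp", "level_cm"), "tide")
  tibble(t = parse_time_col(raw$timestamp), level = raw$level_cm / 100)
}

#' @rdname write_tide
#' @export
write_cloud <- function(cloud, path) {
  readr::write_csv(tibble(timestamp = iso_utc(cloud$t),
                          okta = cloud$okta), path)
  invisible(path)
}

#' @rdname write_tide
#' @export
read_cloud <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(raw, c("timestamp", "okta"), "cloud")
  tibble(t = parse_time_col(raw$timestamp), okta = as.integer(raw$okta))
}

#' @rdname write_tide
#' @export
write_weather <- function(weather, path) {
  readr::write_csv(tibble(timestamp = iso_utc(weather$t),
                          pressure_mb = weather$pressure,
                          rain = weather$rain,
                          wind_speed_ms = weather$wind_speed,
                          wind_dir_deg = weather$wind_dir), path)
  invisible(path)
}

#' @rdname write_tide
#' @export
read_weather <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(raw, c("timestamp", "pressure_mb", "rain", "wind_speed_ms",
                      "wind_dir_deg"), "weather")
  tibble(t = parse_time_col(raw$timestamp), pressure = raw$pressure_mb,
         rain = raw$rain, wind_speed = raw$wind_speed_ms,
         wind_dir = raw$wind_dir_deg)
}

#' Write / read region polygons as GeoJSON
#'
#' A FeatureCollection of two polygon features named `core_area` and
#' `sea_region` (planar metres), with the westward bearing interval kept
#' as a foreign member.
#'
#' @param regions A [region_set()].
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  ring <- function(p) {
    coords <- rbind(as.matrix(p[, c("x", "y")]),
                    as.matrix(p[1, c("x", "y")]))
    list(unname(lapply(seq_len(nrow(coords)),
                       function(i) unname(coords[i, ]))))
  }
  fc <- list(
    type = "FeatureCollection",
    westward_range = regions$westward_range,
    features = lapply(c("core_area", "sea_region"), function(nm) {
      list(type = "Feature", properties = list(name = nm),
           geometry = list(type = "Polygon", coordinates = ring(regions[[nm]])))
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  get_poly <- function(nm) {
    for (f in fc$features) {
      if (identical(f$properties$name, nm)) {
        coords <- f$geometry$coordinates[[1]]
        m <- do.call(rbind, lapply(coords, function(pt)
          c(x = pt[[1]], y = pt[[2]])))
        m <- m[-nrow(m), , drop = FALSE] # drop closing vertex
        return(as_tibble(as.data.frame(m)))
      }
    }
    abort(paste0("polygon ", nm, " not found in ", path),
          class = "knotflight_schema_error")
  }
  region_set(get_poly("core_area"), get_poly("sea_region"),
             westward_range = unlist(fc$westward_range %||% c(225, 315)))
}

#' Pipeline configuration
#'
#' All numeric thresholds of the pipeline in one flat list, with the
#' field defaults: 100 m/s speed filter, 150 m sd filter, 5-fix smoother,
#' 2-h detection gap, 20-min straightness window, 90-degree maximum turn,
#' 0.95 cut-off quantile, 30 available points over 96 h with weight 1000,
#' and 100 bootstrap replicates.
#'
#' @param ... Overrides of the defaults listed above, plus `site_lat`,
#'   `site_lon`, `goal_bearing`, `tide_lag`, `seed`, and the simulation
#'   scenario fields (`n_resident`, `n_departing`, `n_passthrough`,
#'   `start`, `end`, `fix_interval`, `loc_error_sd`).
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    speed_threshold = 100, sd_threshold = 150, smooth_window = 5,
    gap_hours = 2, straightness_window = 20, max_turn = 90,
    transit_speed = 5, cutoff_q = 0.95,
    n_avail = 30, avail_window = 96, avail_weight = 1000, bootstrap_B = 100,
    site_lat = 53.25, site_lon = 5.25, goal_bearing = 262, tide_lag = 30,
    n_resident = 16, n_departing = 10, n_passthrough = 2,
    start = "2019-09-01", end = "2019-09-10",
    fix_interval = 120, loc_error_sd = 25, seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "knotflight_parameter_error")
  }
  cfg[names(dots)] <- dots
  bad <- vapply(cfg[c("speed_threshold", "sd_threshold", "smooth_window",
                      "gap_hours", "straightness_window", "max_turn",
                      "transit_speed", "n_avail", "avail_window",
                      "avail_weight", "bootstrap_B", "fix_interval")],
                function(v) !is.numeric(v) || v <= 0, logical(1))
  if (any(bad) || cfg$cutoff_q <= 0 || cfg$cutoff_q > 1) {
    abort("config thresholds must be positive; cutoff_q in (0, 1]",
          class = "knotflight_parameter_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
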