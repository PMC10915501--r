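# Trajectory cleaning: speed filter, positional-SD filter, running-median
# smoother, applied in that order. Tracks are tibbles with columns
# tag_id, t (POSIXct UTC), x, y, sd; one tag per group.

#' Speed of the segment between two localizations
#'
#' Euclidean distance divided by elapsed time. Vectorized.
#'
#' @param x0,y0 First position (metres).
#' @param t0 First timestamp (POSIXct or numeric seconds).
#' @param x1,y1 Second position (metres).
#' @param t1 Second timestamp; must be strictly later than `t0`.
#' @return Speed in m/s.
#' @examples
#' segment_speed(0, 0, 0, 300, 400, 5) # 100: a 3-4-5 triangle, 500 m in 5 s
#' @export
segment_speed <- function(x0, y0, t0, x1, y1, t1) {
  dt <- as.numeric(t1) - as.numeric(t0)
  if (any(dt <= 0)) {
    abort("segment time delta must be positive (track not time-ordered?)",
          class = "knotflight_ordering_error")
  }
  sqrt((x1 - x0)^2 + (y1 - y0)^2) / dt
}

check_track_cols <- function(tracks, need = c("tag_id", "t", "x", "y")) {
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    abort(paste0("track table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "knotflight_schema_error")
  }
  invisible(tracks)
}

# incoming-segment speeds within one tag (first element NA)
incoming_speeds <- function(t, x, y) {
  n <- length(t)
  if (n < 2) return(rep(NA_real_, n))
  c(NA_real_,
    segment_speed(x[-n], y[-n], t[-n], x[-1], y[-1], t[-1]))
}

#' Remove unrealistic-speed localizations
#'
#' Drops every fix whose incoming-segment speed (from its immediate
#' predecessor in the currently retained sequence) strictly exceeds
#' `threshold`, then recomputes and repeats until no fix is removed. The
#' first fix of each track is always retained; a fix at exactly the
#' threshold is kept.
#'
#' @param tracks Localization tibble (`tag_id`, `t`, `x`, `y`, ...).
#' @param threshold Speed threshold in m/s (default 100, above any
#'   plausible red-knot ground speed).
#' @return The filtered tibble, attribute `n_removed` recording the count.
#' @export
filter_speed <- function(tracks, threshold = 100) {
  check_track_cols(tracks)
  n0 <- nrow(tracks)
  out <- tracks %>%
    group_by(.data$tag_id) %>%
    group_modify(function(df, key) {
      repeat {
        if (nrow(df) < 2) break
        v <- incoming_speeds(df$t, df$x, df$y)
        bad <- !is.na(v) & v > threshold
        if (!any(bad)) break
        df <- df[!bad, , drop = FALSE]
      }
      df
    }) %>%
    ungroup()
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Remove localizations with large positional error
#'
#' Keeps fixes whose positional standard deviation is at most `threshold`
#' metres ("more than" is removed, so the boundary value survives).
#'
#' @param tracks Localization tibble with an `sd` column.
#' @param threshold Metres, default 150.
#' @return Filtered tibble with `n_removed` attribute.
#' @export
filter_sd <- function(tracks, threshold = 150) {
  check_track_cols(tracks, c("tag_id", "t", "x", "y", "sd"))
  if (anyNA(tracks$sd)) {
    i <- which(is.na(tracks$sd))[1]
    abort(paste0("missing positional sd at row ", i,
                 " (tag ", tracks$tag_id[i], ")"),
          class = "knotflight_schema_error")
  }
  out <- filter(tracks, .data$sd <= threshold)
  attr(out, "n_removed") <- nrow(tracks) - nrow(out)
  out
}

#' Running-median smoother
#'
#' Replaces x and y with their running medians over a centered window of
#' `window` fixes. Near track ends the window shrinks symmetrically
#' (the first and last fix are unchanged, the second and penultimate use a
#' window of 3, and so on). Timestamps, sd and track length are unchanged.
#'
#' @param tracks Localization tibble.
#' @param window Odd window size >= 3 (default 5).
#' @return Smoothed tibble.
#' @export
smooth_track <- function(tracks, window = 5) {
  check_track_cols(tracks)
  if (window %% 2 == 0 || window < 3) {
    abort("smoother window must be odd and >= 3",
          class = "knotflight_parameter_error")
  }
  half <- (window - 1L) %/% 2L
  run <- function(z) {
    n <- length(z)
    if (n < 3) return(z)
    vapply(seq_len(n), function(i) {
      h <- min(half, i - 1L, n - i)
      median(z[(i - h):(i + h)])
    }, numeric(1))
  }
  tracks %>%
    group_by(.data$tag_id) %>%
    mutate(x = run(.data$x), y = run(.data$y)) %>%
    ungroup()
}

#' Clean raw localizations
#'
#' The full preprocessing chain in its canonical order: speed filter, then
#' positional-SD filter, then running-median smoother. Per-stage removal
#' counts are returned as the `stage_report` attribute and (optionally)
#' messaged.
#'
#' @param tracks Raw localization tibble (`tag_id`, `t`, `x`, `y`, `sd`).
#' @param speed_threshold m/s, default 100.
#' @param sd_threshold metres, default 150.
#' @param smooth_window odd fix count, default 5.
#' @param verbose Message per-stage counts?
#' @return Cleaned tibble; `attr(, "stage_report")` is a tibble of
#'   stage / n_in / n_removed.
#' @export
preprocess_tracks <- function(tracks, speed_threshold = 100,
                              sd_threshold = 150, smooth_window = 5,
                              verbose = FALSE) {
  check_track_cols(tracks, c("tag_id", "t", "x", "y", "sd"))
  tracks <- arrange(tracks, .data$tag_id, .data$t)
  s1 <- filter_speed(tracks, speed_threshold)
  s2 <- filter_sd(s1, sd_threshold)
  out <- smooth_track(s2, smooth_window)
  report <- tibble(
    stage = c("speed_filter", "sd_filter", "median_smoother"),
    n_in = c(nrow(tracks), nrow(s1), nrow(s2)),
    n_removed = c(attr(s1, "n_removed"), attr(s2, "n_removed"), 0L)
  )
  if (verbose) {
    inform(paste0(report$stage, ": removed ", report$n_removed,
                  " of ", report$n_in, collapse = "; "))
  }
  attr(out, "stage_report") <- report
  out
}
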