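# ggplot2 displays: scaled selection curves for a fitted RSF and a
# track map over the study regions.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_path
#'   geom_polygon facet_wrap labs theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot scaled resource-selection curves
#'
#' One panel per covariate: the scaled selection curve (0-1) with a
#' one-standard-error band around the partial predictor, displayed on
#' the selection scale.
#'
#' @param object An `rsf_fit`.
#' @param covariates Covariates to show; defaults to the smooths plus all
#'   linear terms.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rsf_fit
#' @export
autoplot.rsf_fit <- function(object, covariates = NULL, ...) {
  covariates <- covariates %||% c(object$smooth, object$linear)
  covariates <- setdiff(covariates, "year")
  curves <- list_rbind(lapply(covariates, function(v) rsf_curve(object, v)))
  # se band on the selection scale, rescaled with the same min-max as rsf
  curves <- curves %>%
    group_by(.data$covariate) %>%
    mutate(
      lo = pmax(0, .data$rsf * exp(-.data$se)),
      hi = pmin(1, .data$rsf * exp(.data$se))
    ) %>%
    ungroup()
  ggplot(curves, aes(x = .data$value, y = .data$rsf)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi),
                fill = "grey80") +
    geom_line() +
    facet_wrap(~covariate, scales = "free_x") +
    labs(x = NULL, y = "scaled selection") +
    theme_minimal()
}

#' Plot tracks over the study regions
#'
#' @param tracks Localization tibble.
#' @param regions A [region_set()].
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, regions) {
  check_track_cols(tracks)
  polys <- bind_rows(
    mutate(regions$core_area, region = "core_area"),
    mutate(regions$sea_region, region = "sea_region")
  )
  ggplot() +
    geom_polygon(data = polys,
                 aes(x = .data$x, y = .data$y, group = .data$region),
                 fill = NA, colour = "grey40") +
    geom_path(data = tracks,
              aes(x = .data$x, y = .data$y, colour = .data$tag_id),
              show.legend = FALSE) +
    coord_equal() +
    labs(x = "x (m east)", y = "y (m north)") +
    theme_minimal()
}
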