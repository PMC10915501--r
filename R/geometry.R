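# Planar geometry helpers shared by the track classifier and the simulator.
# Coordinates are metres in a local projected frame (x east, y north);
# bearings are compass degrees (0 = north, clockwise).

#' Compass bearing between two planar points
#'
#' @param x0,y0 Coordinates of the start point (metres).
#' @param x1,y1 Coordinates of the end point (metres).
#' @return Bearing in degrees within `[0, 360)`; 0 is due north (+y),
#'   90 due east. Vectorized over all arguments.
#' @examples
#' bearing(0, 0, 0, 1)   # 0, due north
#' bearing(0, 0, -1, 0)  # 270, due west
#' @export
bearing <- function(x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  if (any(dx == 0 & dy == 0)) {
    abort("bearing undefined for coincident points",
          class = "knotflight_geometry_error")
  }
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' Smallest angular difference between two bearings
#'
#' @param b1,b2 Bearings in degrees.
#' @return Absolute circular difference in degrees, within `[0, 180]`.
#' @examples
#' angular_difference(350, 10) # 20
#' @export
angular_difference <- function(b1, b2) {
  d <- abs(b1 - b2) %% 360
  pmin(d, 360 - d)
}

#' Test points against a polygon
#'
#' Point-in-polygon with the package's boundary convention: a point exactly
#' on the boundary counts as inside.
#'
#' @param x,y Point coordinates (metres).
#' @param polygon A data frame or matrix with columns `x`, `y` listing the
#'   polygon vertices in order (closed or open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  poly <- as.data.frame(polygon)
  if (!all(c("x", "y") %in% names(poly)) || nrow(poly) < 3) {
    abort("polygon must have columns x, y and at least 3 vertices",
          class = "knotflight_geometry_error")
  }
  pracma::inpolygon(x, y, poly$x, poly$y, boundary = TRUE)
}

#' Construct a rectangular polygon
#'
#' Convenience constructor used for the synthetic core-area and sea-region
#' polygons.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @return A tibble of 4 vertices (columns `x`, `y`), counter-clockwise.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  tibble(x = c(xmin, xmax, xmax, xmin),
         y = c(ymin, ymin, ymax, ymax))
}

#' Region set for departure classification
#'
#' Bundles the core tracking-area polygon, the sea-region polygon, and the
#' bearing interval that counts as "westward".
#'
#' @param core_area,sea_region Polygons (data frames with `x`, `y`).
#' @param westward_range Numeric length-2, inclusive bearing interval in
#'   degrees; default `c(225, 315)`.
#' @return An object of class `region_set`.
#' @export
region_set <- function(core_area, sea_region, westward_range = c(225, 315)) {
  for (p in list(core_area, sea_region)) {
    if (!all(c("x", "y") %in% names(as.data.frame(p))) ||
        nrow(as.data.frame(p)) < 3) {
      abort("polygons must have columns x, y and >= 3 vertices",
            class = "knotflight_geometry_error")
    }
  }
  if (length(westward_range) != 2 || any(westward_range < 0) ||
      any(westward_range >= 360) || westward_range[1] > westward_range[2]) {
    abort("westward_range must be an ordered interval within [0, 360)",
          class = "knotflight_geometry_error")
  }
  structure(list(core_area = as_tibble(core_area),
                 sea_region = as_tibble(sea_region),
                 westward_range = westward_range),
            class = "region_set")
}
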