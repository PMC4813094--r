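#' Rectangular study region with three administrative zones
#'
#' The synthetic study domain: a planar rectangle (km coordinates) split into
#' three named vertical bands standing in for a country's administrative
#' zones, with a regular pixel grid for prediction and aggregation.
#'
#' @param width_km,height_km region extent in km; must be positive.
#' @param resolution_km pixel size in km; must be positive.
#' @return An object of class \code{wm_region}: bounding box, zone polygons
#'   (closed rectangles, named), and pixel-grid geometry.
#' @examples
#' r <- make_study_region(300, 300, 10)
#' length(region_pixel_xs(r)) # 30
#' @export
make_study_region <- function(width_km, height_km, resolution_km) {
  if (!is.numeric(width_km) || width_km <= 0 ||
      !is.numeric(height_km) || height_km <= 0) {
    stop("width_km and height_km must be positive", call. = FALSE)
  }
  if (!is.numeric(resolution_km) || resolution_km <= 0) {
    stop("resolution_km must be positive", call. = FALSE)
  }
  zone_names <- c("north_west", "south_central", "north_east")
  cuts <- c(0, width_km / 3, 2 * width_km / 3, width_km)
  zones <- lapply(1:3, function(i) {
    rbind(c(cuts[i], 0), c(cuts[i + 1], 0),
          c(cuts[i + 1], height_km), c(cuts[i], height_km), c(cuts[i], 0))
  })
  names(zones) <- zone_names
  nx <- max(1L, as.integer(ceiling(width_km / resolution_km - 1e-9)))
  ny <- max(1L, as.integer(ceiling(height_km / resolution_km - 1e-9)))
  structure(list(
    xlim = c(0, width_km), ylim = c(0, height_km),
    resolution = resolution_km,
    zones = zones, zone_cuts = cuts,
    nx = nx, ny = ny
  ), class = "wm_region")
}

#' @export
print.wm_region <- function(x, ...) {
  cat(sprintf("<wm_region> %g x %g km, %d x %d pixels at %g km, zones: %s\n",
              diff(x$xlim), diff(x$ylim), x$nx, x$ny, x$resolution,
              paste(names(x$zones), collapse = ", ")))
  invisible(x)
}

#' Pixel-centre coordinates of a region's grid
#'
#' @param region a [make_study_region()] object.
#' @return numeric vector of pixel-centre x (or y) coordinates in km.
#' @export
region_pixel_xs <- function(region) {
  region$resolution * (seq_len(region$nx) - 0.5)
}

#' @rdname region_pixel_xs
#' @export
region_pixel_ys <- function(region) {
  region$resolution * (seq_len(region$ny) - 0.5)
}

#' Empty grid matching a region's pixel geometry
#'
#' @param region a [make_study_region()] object.
#' @param fill fill value.
#' @return a [pixel_grid()].
#' @export
region_grid <- function(region, fill = 0) {
  xs <- region_pixel_xs(region); ys <- region_pixel_ys(region)
  pixel_grid(xs, ys, matrix(fill, length(xs), length(ys)))
}

#' Zone membership of points
#'
#' @param region a [make_study_region()] object.
#' @param x,y coordinates in km.
#' @return character vector of zone names; \code{NA} outside the region.
#' @export
zone_of <- function(region, x, y) {
  inside <- x >= region$xlim[1] & x <= region$xlim[2] &
    y >= region$ylim[1] & y <= region$ylim[2]
  band <- findInterval(x, region$zone_cuts, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1L), 3L)
  out <- names(region$zones)[band]
  out[!inside] <- NA_character_
  out
}

#' Zone areas
#'
#' @param region a [make_study_region()] object.
#' @return named numeric vector of zone areas (km^2); they sum to the region
#'   area by construction.
#' @export
zone_areas <- function(region) {
  vapply(region$zones, function(p) {
    # shoelace on the closed polygon
    n <- nrow(p) - 1L
    abs(sum(p[1:n, 1] * p[2:(n + 1), 2] - p[2:(n + 1), 1] * p[1:n, 2])) / 2
  }, numeric(1))
}
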