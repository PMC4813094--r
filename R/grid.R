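#' Pixel grid container
#'
#' A regular raster of pixel-centre values on planar (km) coordinates.
#' \code{values} is an \code{nx x ny} matrix: rows follow \code{xs}, columns
#' follow \code{ys}. This is the package's in-memory raster; on disk it is the
#' headered CSV dialect of [write_grid_csv()].
#'
#' @param xs,ys strictly increasing pixel-centre coordinates (km).
#' @param values numeric matrix of dimension \code{length(xs) x length(ys)}.
#' @return An object of class \code{wm_grid}.
#' @export
pixel_grid <- function(xs, ys, values) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) > 1 && any(diff(xs) <= 0)) stop("xs must be strictly increasing")
  if (length(ys) > 1 && any(diff(ys) <= 0)) stop("ys must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != length(xs) || ncol(values) != length(ys)) {
    stop(sprintf("values must be %d x %d, got %d x %d",
                 length(xs), length(ys), nrow(values), ncol(values)))
  }
  structure(list(xs = xs, ys = ys, values = values), class = "wm_grid")
}

#' @export
print.wm_grid <- function(x, ...) {
  cat(sprintf("<wm_grid> %d x %d pixels, x in [%g, %g], y in [%g, %g]\n",
              length(x$xs), length(x$ys), min(x$xs), max(x$xs),
              min(x$ys), max(x$ys)))
  cat(sprintf("  values: [%g, %g]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Pixel centres of a grid as a data frame
#'
#' Row-major order: y varies slowest, x fastest, matching the CSV dialect.
#'
#' @param grid a [pixel_grid()].
#' @return data.frame with columns \code{x}, \code{y}, \code{value}.
#' @export
grid_df <- function(grid) {
  stopifnot(inherits(grid, "wm_grid"))
  data.frame(
    x = rep(grid$xs, times = length(grid$ys)),
    y = rep(grid$ys, each = length(grid$xs)),
    value = as.vector(grid$values)
  )
}

#' Nearest-pixel lookup
#'
#' @param grid a [pixel_grid()].
#' @param x,y coordinate vectors (km).
#' @return vector of pixel values at the nearest pixel centre.
#' @export
grid_lookup <- function(grid, x, y) {
  ix <- pmin(pmax(findInterval(x, grid$xs + c(diff(grid$xs) / 2, Inf)) + 1L, 1L),
             length(grid$xs))
  iy <- pmin(pmax(findInterval(y, grid$ys + c(diff(grid$ys) / 2, Inf)) + 1L, 1L),
             length(grid$ys))
  grid$values[cbind(ix, iy)]
}

same_geometry <- function(a, b, tol = 1e-9) {
  length(a$xs) == length(b$xs) && length(a$ys) == length(b$ys) &&
    max(abs(a$xs - b$xs)) <= tol && max(abs(a$ys - b$ys)) <= tol
}

#' Write / read a grid as headered CSV
#'
#' The plain-text raster interchange: a comment metadata line, then header
#' \code{x,y,value} and one row per pixel in row-major order (y slowest).
#' Round-trips values to better than 1e-9 and geometry exactly.
#'
#' @param grid a [pixel_grid()].
#' @param path file path.
#' @param metadata optional named list merged into the metadata comment.
#' @return \code{write_grid_csv}: the path, invisibly. \code{read_grid_csv}:
#'   a [pixel_grid()].
#' @export
write_grid_csv <- function(grid, path, metadata = NULL) {
  stopifnot(inherits(grid, "wm_grid"))
  meta <- c(pkg_metadata(), metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  df <- grid_df(grid)
  writeLines("x,y,value", con)
  writeLines(sprintf("%.12g,%.12g,%.12g", df$x, df$y, df$value), con)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x", "y", "value")
  if (!all(need %in% names(df))) {
    stop("grid CSV must have columns x,y,value; got: ",
         paste(names(df), collapse = ", "))
  }
  xs <- sort(unique(df$x))
  ys <- sort(unique(df$y))
  if (nrow(df) != length(xs) * length(ys)) {
    stop("grid CSV is not a complete rectangular grid")
  }
  ix <- match(df$x, xs); iy <- match(df$y, ys)
  values <- matrix(NA_real_, length(xs), length(ys))
  values[cbind(ix, iy)] <- df$value
  pixel_grid(xs, ys, values)
}
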