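# Shared geometry helpers.
#
# Coordinate convention used throughout the package: x = image column,
# y = image row, origin at the top-left pixel, 0-based, pixel centers at
# integer coordinates.  No sub-pixel refinement is performed anywhere.

#' Euclidean norm of a 2-D vector
#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

#' Euclidean distance between two 2-D points
#' @noRd
pdist <- function(a, b) sqrt(sum((a - b)^2))

#' Length of an open polyline given as an n x 2 matrix
#' @noRd
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Length of the closed polygon through the rows of `pts`
#' @noRd
polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  polyline_length(rbind(pts, pts[1L, , drop = FALSE]))
}

#' Signed area of a closed polygon (shoelace formula, image coordinates)
#' @noRd
polygon_signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Test whether points lie inside or on a closed polygon
#'
#' Thin wrapper around [pracma::inpolygon()] fixing the package's boundary
#' semantics (boundary points count as inside).
#'
#' @param px,py numeric vectors of query point coordinates.
#' @param poly n x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = TRUE)
}

#' Resample an open polyline to `k` points, equidistant in arc length
#'
#' Linear interpolation between the original vertices; the first and last
#' points are preserved exactly.
#'
#' @param pts n x 2 matrix (n >= 1).
#' @param k target number of points (k >= 2).
#' @return k x 2 matrix.
#' @keywords internal
resample_polyline <- function(pts, k) {
  stopifnot(k >= 2L)
  n <- nrow(pts)
  if (n == 1L) return(pts[rep(1L, k), , drop = FALSE])
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n]
  if (total == 0) return(pts[rep(1L, k), , drop = FALSE])
  target <- seq(0, total, length.out = k)
  x <- stats::approx(cum, pts[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(cum, pts[, 2L], xout = target, ties = "ordered")$y
  cbind(x, y, deparse.level = 0)
}

#' Encode integer pixel coordinates as single keys for fast set operations
#' @noRd
pixel_keys <- function(pixels) {
  # pixels: m x 2 integer matrix (x, y); key stride comfortably exceeds any
  # realistic image dimension
  as.numeric(pixels[, 1L]) * 1e6 + as.numeric(pixels[, 2L])
}
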