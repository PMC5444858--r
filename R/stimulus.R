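# Stimulus-marker geometry: nearest point, distance, bearing, region
# membership.  Marker coordinates live in the same pixel frame as the
# images.

new_marker <- function(kind, id, params) {
  structure(c(list(kind = kind, id = id), params), class = "lt_marker")
}

#' Stimulus markers
#'
#' Four marker shapes are supported: a point, a straight line segment,
#' an axis-aligned rectangle and an axis-aligned ellipse.  Markers are
#' supplied via the configuration file or constructed directly; each
#' carries an `id` under which its features appear in the output table
#' (`dist_to_<id>`, `bearing_<id>`, `in_<id>`).
#'
#' @param id label used in output column names.
#' @param x,y point coordinates.
#' @return object of class `lt_marker`.
#' @export
stim_point <- function(id, x, y) new_marker("point", id, list(p = c(x, y)))

#' @rdname stim_point
#' @param x1,y1,x2,y2 segment endpoints.
#' @export
stim_line <- function(id, x1, y1, x2, y2)
  new_marker("line", id, list(p1 = c(x1, y1), p2 = c(x2, y2)))

#' @rdname stim_point
#' @param xmin,ymin,xmax,ymax ordered rectangle corners.
#' @export
stim_rect <- function(id, xmin, ymin, xmax, ymax) {
  stopifnot(xmin <= xmax, ymin <= ymax)
  new_marker("rectangle", id, list(xmin = xmin, ymin = ymin,
                                   xmax = xmax, ymax = ymax))
}

#' @rdname stim_point
#' @param cx,cy ellipse center.
#' @param a,b semi-axes (> 0) along x and y.
#' @export
stim_ellipse <- function(id, cx, cy, a, b) {
  stopifnot(a > 0, b > 0)
  new_marker("ellipse", id, list(c = c(cx, cy), a = a, b = b))
}

#' @export
print.lt_marker <- function(x, ...) {
  cat(sprintf("<stimulus marker '%s' (%s)>\n", x$id, x$kind))
  invisible(x)
}

# orthogonal projection of m onto the segment p1-p2, with the off-segment
# clamp: if the projection leaves the segment, take the endpoint nearest
# to the projected point
project_on_segment <- function(p1, p2, m) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) return(p1)
  t <- sum((m - p1) * d) / len2
  proj <- p1 + t * d
  if (t >= 0 && t <= 1) return(proj)
  if (pdist(proj, p1) <= pdist(proj, p2)) p1 else p2
}

#' Nearest point on a stimulus marker
#'
#' Point: the point itself.  Line: orthogonal projection of `m` onto the
#' carrier line, clamped to the nearer endpoint when it falls off the
#' segment.  Rectangle: the minimum-distance projection among the four
#' boundary edges.  Ellipse: approximation by the nearer of the two
#' intersections of the line through `m` and the center with the ellipse
#' boundary (the exact point-to-ellipse problem is a quartic; the
#' approximation is exact for circles and for points on the axes).
#'
#' @param marker `lt_marker`.
#' @param m (x, y) query point (an animal's center of mass).
#' @return (x, y) point on the marker boundary (or the marker point).
#' @export
nearest_point <- function(marker, m) {
  switch(marker$kind,
    point = marker$p,
    line = project_on_segment(marker$p1, marker$p2, m),
    rectangle = {
      corners <- list(c(marker$xmin, marker$ymin), c(marker$xmax, marker$ymin),
                      c(marker$xmax, marker$ymax), c(marker$xmin, marker$ymax))
      best <- NULL; bestd <- Inf
      for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))) {
        p <- project_on_segment(corners[[e[1L]]], corners[[e[2L]]], m)
        d <- pdist(m, p)
        if (d < bestd) { bestd <- d; best <- p }
      }
      best
    },
    ellipse = {
      u <- m - marker$c
      if (vnorm(u) == 0) {
        warning("query point at ellipse center; returning boundary point on the positive x/y semi-axis")
        return(if (marker$a <= marker$b) marker$c + c(marker$a, 0)
               else marker$c + c(0, marker$b))
      }
      u <- u / vnorm(u)
      t <- 1 / sqrt((u[1L] / marker$a)^2 + (u[2L] / marker$b)^2)
      marker$c + t * u          # intersection on the same side as m
    },
    stop("unknown marker kind: ", marker$kind))
}

#' Distance from a point to a stimulus marker
#'
#' Euclidean distance between `m` and [nearest_point()].
#'
#' @inheritParams nearest_point
#' @return distance in px.
#' @export
stimulus_distance <- function(marker, m) pdist(m, nearest_point(marker, m))

#' Bearing angle toward a stimulus
#'
#' Unsigned angle at the tail between v1 = m - t and v2 = p - t, where
#' p is the nearest marker point.  The tail anchors the body axis
#' because it is unaffected by head casts.
#'
#' @param m center of mass.
#' @param tail tail point.
#' @param p nearest marker point (from [nearest_point()]).
#' @return angle in degrees in [0, 180]; NA for degenerate vectors.
#' @export
bearing_angle <- function(m, tail, p) {
  v1 <- m - tail
  v2 <- p - tail
  n1 <- vnorm(v1); n2 <- vnorm(v2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Is a point inside the stimulus region?
#'
#' Point: coincidence; line: within half a pixel of the segment;
#' rectangle and ellipse: closed standard inclusion tests.
#'
#' @inheritParams nearest_point
#' @return logical.
#' @export
in_region <- function(marker, m) {
  switch(marker$kind,
    point = isTRUE(all.equal(as.numeric(marker$p), as.numeric(m))),
    line = pdist(m, project_on_segment(marker$p1, marker$p2, m)) <= 0.5,
    rectangle = m[1L] >= marker$xmin && m[1L] <= marker$xmax &&
                m[2L] >= marker$ymin && m[2L] <= marker$ymax,
    ellipse = ((m[1L] - marker$c[1L]) / marker$a)^2 +
              ((m[2L] - marker$c[2L]) / marker$b)^2 <= 1,
    stop("unknown marker kind: ", marker$kind))
}
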