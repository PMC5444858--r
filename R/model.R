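# Posture-model extraction: one filtered contour -> head, spine points
# with radii, tail, center of mass.

#' Model-extraction parameters
#'
#' @param n_spine_points total number of midline landmarks L including
#'   head and tail; the interior spine then has L - 2 points.  The
#'   default 7 gives 5 interior points.
#' @param curvature_window half-size w of the sliding window used to
#'   average curvature angles; the window spans 2w + 1 contour points.
#' @param head_tail_min_separation_frac minimal circular index distance
#'   between the head and tail candidates, as a fraction of the contour
#'   point count.
#' @param d_min,d_max base arm lengths (in contour points) for the
#'   curvature triangles; both are rescaled with contour length (see
#'   [contour_curvature()]).
#' @return object of class `lt_model_config`.
#' @export
model_config <- function(n_spine_points = 7L, curvature_window = 2L,
                         head_tail_min_separation_frac = 0.25,
                         d_min = 4L, d_max = 7L) {
  stopifnot(n_spine_points >= 3L, curvature_window >= 1L,
            head_tail_min_separation_frac > 0,
            head_tail_min_separation_frac < 0.5,
            d_min >= 2L, d_max >= d_min)
  structure(list(n_spine_points = as.integer(n_spine_points),
                 curvature_window = as.integer(curvature_window),
                 head_tail_min_separation_frac = head_tail_min_separation_frac,
                 d_min = as.integer(d_min), d_max = as.integer(d_max)),
            class = "lt_model_config")
}

#' Animal posture model
#'
#' @param head,tail (x, y) endpoint landmarks.
#' @param spine (L - 2) x 2 matrix of interior midline points ordered
#'   from the head side to the tail side.
#' @param radii local half-widths at each spine point (> 0).
#' @param com (x, y) center of mass (centroid of the enclosed pixel
#'   region, rounded to integer coordinates).
#' @param contour source [lt_contour()]; `area` and `perimeter` are
#'   copied from it.
#' @return object of class `lt_model`.
#' @export
lt_model <- function(head, tail, spine, radii, com, contour) {
  stopifnot(nrow(spine) == length(radii), nrow(spine) >= 1L, all(radii > 0))
  structure(list(head = as.numeric(head), tail = as.numeric(tail),
                 spine = spine, radii = as.numeric(radii),
                 com = as.numeric(com),
                 area = contour$area, perimeter = contour$perimeter,
                 contour = contour),
            class = "lt_model")
}

#' @export
print.lt_model <- function(x, ...) {
  cat(sprintf(paste0("<animal model: head (%.0f,%.0f), tail (%.0f,%.0f), ",
                     "%d spine points, area %d px>\n"),
              x$head[1L], x$head[2L], x$tail[1L], x$tail[2L],
              nrow(x$spine), x$area))
  invisible(x)
}

#' All landmark points of a model as one matrix (head, spine, tail, com)
#' @param model [lt_model()].
#' @return n x 2 matrix.
#' @export
model_points <- function(model) {
  rbind(model$head, model$spine, model$tail, model$com, deparse.level = 0)
}

# Arm lengths for the curvature triangles, rescaled with contour size and
# clamped so they stay meaningful on small contours.
curvature_arms <- function(n_points, config) {
  if ((n_points - 1L) %/% 2L < 2L)
    stop("contour too short for curvature estimation")
  scale <- n_points / 100
  dmin <- max(2L, as.integer(round(config$d_min * scale)))
  dmax <- max(dmin, as.integer(round(config$d_max * scale)))
  # arms must fit the circular contour with room for distinct flanks
  dmax <- min(dmax, (n_points - 1L) %/% 2L)
  dmin <- min(dmin, dmax)
  c(dmin = dmin, dmax = dmax)
}

#' Per-point curvature angles on a closed contour
#'
#' First pass of the IPAN corner detector: at each contour point p the
#' angle of the triangle (p_minus, p, p_plus) is evaluated for all flank
#' offsets within the admissible arm-length band, and the sharpest
#' (smallest) admissible angle is kept.  Small angles mark sharp
#' protrusions such as the head and tail tips.
#'
#' @param contour [lt_contour()].
#' @param config [lt_model_config()]; arm lengths `d_min`/`d_max` are
#'   rescaled by contour length / 100 and clamped to at least 2.
#' @return numeric vector of angles in degrees, aligned with
#'   `contour$points`.
#' @export
contour_curvature <- function(contour, config = model_config()) {
  pts <- contour$points
  n <- nrow(pts)
  arms <- curvature_arms(n, config)
  if (n < 2L * arms[["dmax"]] + 1L || arms[["dmin"]] < 1L)
    stop("contour too short for curvature estimation")
  x <- pts[, 1L]; y <- pts[, 2L]
  best <- rep(Inf, n)
  idx <- seq_len(n)
  for (a in arms[["dmin"]]:arms[["dmax"]]) {
    for (b in arms[["dmin"]]:arms[["dmax"]]) {
      ia <- ((idx - 1L + a) %% n) + 1L
      ib <- ((idx - 1L - b) %% n) + 1L
      v1x <- x[ia] - x; v1y <- y[ia] - y
      v2x <- x[ib] - x; v2y <- y[ib] - y
      num <- v1x * v2x + v1y * v2y
      den <- sqrt((v1x^2 + v1y^2) * (v2x^2 + v2y^2))
      cosang <- pmin(1, pmax(-1, num / den))
      ang <- acos(cosang) * 180 / pi
      best <- pmin(best, ang)
    }
  }
  best
}

# circular rolling mean with window 2w + 1
circular_window_mean <- function(v, w) {
  as.numeric(stats::filter(v, rep(1 / (2 * w + 1), 2 * w + 1),
                           method = "convolution", sides = 2, circular = TRUE))
}

#' Locate provisional head and tail on a contour
#'
#' A window of size 2w + 1 slides over the circular curvature sequence;
#' the center of the window with the sharpest (minimum) mean angle is the
#' provisional head, and the sharpest remaining center at circular index
#' distance of at least the configured separation is the provisional
#' tail.  Curvature alone cannot distinguish head from tail reliably;
#' the final orientation is owned by the trajectory-level post-processing.
#'
#' @param contour [lt_contour()].
#' @param curvatures output of [contour_curvature()] for this contour.
#' @param config [lt_model_config()].
#' @return integer vector `c(head = i, tail = j)` of 1-based indices into
#'   `contour$points`.
#' @export
locate_head_tail <- function(contour, curvatures, config = model_config()) {
  n <- nrow(contour$points)
  stopifnot(length(curvatures) == n)
  means <- circular_window_mean(curvatures, config$curvature_window)
  head_idx <- which.min(means)
  sep <- max(1L, as.integer(round(config$head_tail_min_separation_frac * n)))
  d <- abs(seq_len(n) - head_idx)
  circ_dist <- pmin(d, n - d)
  cand <- which(circ_dist >= sep)
  if (length(cand) == 0L)
    stop("degenerate contour: no tail candidate at the required separation")
  tail_idx <- cand[which.min(means[cand])]
  c(head = head_idx, tail = tail_idx)
}

# Normalize contour orientation: positive shoelace signed area in image
# coordinates (y down).  Splitting is then deterministic.
normalize_ccw <- function(points) {
  if (polygon_signed_area(points) < 0) points[rev(seq_len(nrow(points))), , drop = FALSE]
  else points
}

#' Split a contour at head and tail and equalize the halves
#'
#' The closed contour is cut at the head and tail indices into two open
#' chains, both running from head to tail.  The longer chain is linearly
#' resampled (arc-length parameterization) to the point count of the
#' shorter, so that each point on one half pairs with a unique point on
#' the other.
#'
#' @param contour [lt_contour()] (orientation irrelevant; indices refer
#'   to `contour$points` as stored).
#' @param head_index,tail_index 1-based indices from [locate_head_tail()].
#' @return list `(half1, half2)` of k x 2 matrices, equal length, both
#'   starting at the head point and ending at the tail point.
#' @export
split_and_resample <- function(contour, head_index, tail_index) {
  stopifnot(head_index != tail_index)
  pts <- contour$points
  n <- nrow(pts)
  fwd <- if (head_index <= tail_index) head_index:tail_index
         else c(head_index:n, 1L:tail_index)
  bwd_rev <- if (tail_index <= head_index) tail_index:head_index
             else c(tail_index:n, 1L:head_index)
  bwd <- rev(bwd_rev)                      # head -> tail along the other side
  c1 <- pts[fwd, , drop = FALSE]
  c2 <- pts[bwd, , drop = FALSE]
  k <- min(nrow(c1), nrow(c2))
  k <- max(k, 2L)
  if (nrow(c1) != k) c1 <- resample_polyline(c1, k)
  if (nrow(c2) != k) c2 <- resample_polyline(c2, k)
  list(half1 = c1, half2 = c2)
}

#' Build the full posture model from one contour
#'
#' Pipeline: curvature (IPAN pass 1) -> provisional head/tail ->
#' contour split and resampling -> L - 2 pairs at equidistant arc-length
#' positions (endpoints excluded, fractional indices rounded down).
#' Each spine point is the midpoint of its pair, each radius half the
#' pair distance; the center of mass is the centroid of the enclosed
#' pixel region, rounded to integer coordinates.
#'
#' @param contour [lt_contour()].
#' @param config [lt_model_config()].
#' @return [lt_model()].
#' @export
build_model <- function(contour, config = model_config()) {
  contour$points <- normalize_ccw(contour$points)
  curv <- contour_curvature(contour, config)
  ht <- locate_head_tail(contour, curv, config)
  halves <- split_and_resample(contour, ht[["head"]], ht[["tail"]])
  c1 <- halves$half1; c2 <- halves$half2
  k <- nrow(c1)
  n_interior <- config$n_spine_points - 2L
  # equidistant arc-length positions along half1, endpoints excluded
  seg <- sqrt(rowSums((c1[-1L, , drop = FALSE] - c1[-k, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[k]
  targets <- total * seq_len(n_interior) / (n_interior + 1L)
  pick <- vapply(targets, function(tt) max(which(cum <= tt + 1e-9)), integer(1L))
  pick <- pmin(pmax(pick, 2L), k - 1L)
  p1 <- c1[pick, , drop = FALSE]
  p2 <- c2[pick, , drop = FALSE]
  spine <- (p1 + p2) / 2
  radii <- pmax(sqrt(rowSums((p1 - p2)^2)) / 2, 0.5)   # floor: half a pixel
  com <- round(contour$centroid)
  lt_model(head = contour$points[ht[["head"]], ],
           tail = contour$points[ht[["tail"]], ],
           spine = spine, radii = radii, com = com, contour = contour)
}

#' Extract models for every filtered contour of a foreground image
#'
#' Contours whose model extraction fails (degenerate shapes) are skipped
#' with a warning.
#'
#' @param contours list of [lt_contour()].
#' @param config [lt_model_config()].
#' @return list of [lt_model()].
#' @export
build_models <- function(contours, config = model_config()) {
  out <- list()
  for (ct in contours) {
    m <- tryCatch(build_model(ct, config), error = function(e) {
      warning("skipping contour: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(m)) out[[length(out) + 1L]] <- m
  }
  out
}
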