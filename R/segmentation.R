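# Segmentation: raw frames -> filtered single-animal contours.
#
# Frames are numeric matrices indexed [row, col] with intensities in
# [0, 255]; points exposed to the user are (x, y) = (col - 1, row - 1),
# 0-based (see geometry.R).

#' Segmentation parameters
#'
#' @param gray_threshold intensity offset tau added to the per-pixel
#'   background; a pixel is foreground when its intensity exceeds the
#'   background by at least this amount.
#' @param area_min,area_max area band (in pixels) for single animals;
#'   smaller contours are treated as artifacts, larger ones as colliding
#'   animals, and both are discarded.
#' @return object of class `lt_seg_config`.
#' @export
seg_config <- function(gray_threshold = 40, area_min = 60, area_max = 1500) {
  stopifnot(gray_threshold >= 0, gray_threshold <= 255,
            area_min > 0, area_min < area_max)
  structure(list(gray_threshold = gray_threshold,
                 area_min = area_min, area_max = area_max),
            class = "lt_seg_config")
}

#' Contour constructor
#'
#' A contour is the closed outer boundary of one connected foreground
#' component, together with the pixel region it encloses.
#'
#' @param points n x 2 matrix of ordered (x, y) boundary positions.
#' @param pixels m x 2 integer matrix of all enclosed pixel coordinates
#'   (the component itself); used for area, centroid and overlap costs.
#' @return object of class `lt_contour` with fields `points`, `pixels`,
#'   `area` (enclosed pixel count), `perimeter` (closed boundary length)
#'   and `centroid` (pixel-mean, unrounded).
#' @export
lt_contour <- function(points, pixels) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 3L,
            is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  structure(list(points = points,
                 pixels = pixels,
                 area = nrow(pixels),
                 perimeter = polygon_perimeter(points),
                 centroid = unname(colMeans(pixels))),
            class = "lt_contour")
}

#' @export
print.lt_contour <- function(x, ...) {
  cat(sprintf("<contour: %d boundary points, area %d px, perimeter %.1f px>\n",
              nrow(x$points), x$area, x$perimeter))
  invisible(x)
}

check_frame_stack <- function(frames) {
  if (length(frames) == 0L) stop("empty frame sequence")
  d <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f)) stop("frames must be matrices")
    if (!identical(dim(f), d)) stop("frame dimensions differ within sequence")
  }
  invisible(d)
}

#' Static background as the per-pixel minimum over time
#'
#' Animals are bright on a near-black background and move by more than
#' their own body length over a recording, so the minimum intensity each
#' pixel ever takes is a background estimate that retains static
#' artifacts (which are then removed by subtraction).
#'
#' @param frames list of intensity matrices with identical dimensions.
#' @param stride use every `stride`-th frame (default 1 = all frames).
#'   A subsampled minimum is an upper bound of the full minimum; it
#'   bounds memory/time on long recordings at the price of possibly
#'   retaining slightly more foreground.
#' @return matrix of the same dimensions.
#' @export
compute_background <- function(frames, stride = 1L) {
  check_frame_stack(frames)
  stopifnot(stride >= 1L)
  idx <- seq(1L, length(frames), by = stride)
  Reduce(pmin, frames[idx])
}

#' Foreground by thresholded background subtraction
#'
#' Pixels whose intensity differs from the background by at least
#' `gray_threshold` keep their ORIGINAL intensity; all others are set to
#' zero.  The result is an intensity image, not a binary mask.
#'
#' @param frame,background intensity matrices of identical dimensions.
#' @param config [seg_config()].
#' @return foreground intensity matrix.
#' @export
extract_foreground <- function(frame, background, config = seg_config()) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  out <- frame
  out[abs(frame - background) < config$gray_threshold] <- 0
  out
}

# 8-connected component labels: EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged with a union-find pass.
label_components8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary)))
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]     # down-right diagonal
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]     # down-left diagonal
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Trace outer contours of all foreground components
#'
#' One closed outer boundary per 8-connected component of the nonzero
#' pixels (border following; holes inside bodies are ignored as
#' segmentation noise).  Components whose boundary degenerates to fewer
#' than 3 points (1-2 isolated pixels) are dropped.
#'
#' @param foreground intensity matrix; zeros are background.
#' @return list of [lt_contour()] objects (empty list for an empty image).
#' @export
find_contours <- function(foreground) {
  stopifnot(is.matrix(foreground))
  binary <- (foreground > 0) * 1L
  if (!any(binary > 0L)) return(list())
  lab <- label_components8(binary)
  # transpose so that EBImage's first dimension is the image x (column) axis;
  # ocontour then yields 0-based (x, y) traces directly
  traces <- EBImage::ocontour(EBImage::Image(t(lab)))
  out <- list()
  for (nm in names(traces)) {
    k <- as.integer(nm)
    pts <- traces[[nm]]
    if (nrow(pts) < 3L) next
    rc <- which(lab == k, arr.ind = TRUE)           # 1-based (row, col)
    pixels <- cbind(x = rc[, 2L] - 1L, y = rc[, 1L] - 1L)
    out[[length(out) + 1L]] <- lt_contour(pts, pixels)
  }
  out
}

#' Keep contours whose area falls in the single-animal band
#'
#' Contours with area above `area_max` are presumed collisions, below
#' `area_min` presumed artifacts; both are removed.
#'
#' @param contours list of [lt_contour()].
#' @param config [seg_config()].
#' @return filtered list (subset of the input, order preserved).
#' @export
filter_contours <- function(contours, config = seg_config()) {
  keep <- vapply(contours, function(ct)
    ct$area >= config$area_min && ct$area <= config$area_max, logical(1L))
  contours[keep]
}
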