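# Independent oracles and fixture builders shared by the test files.
# Everything here is deliberately naive (brute force, enumeration,
# flood fill) and independent of the implementation paths it checks.

# --- brute-force assignment -------------------------------------------------

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# best total over all injections of rows into columns (or vice versa)
oracle_assignment_cost <- function(a, maximize = FALSE) {
  nr <- nrow(a); nc <- ncol(a)
  best <- if (maximize) -Inf else Inf
  if (nr <= nc) {
    for (cols in utils::combn(nc, nr, simplify = FALSE))
      for (p in perms(cols)) {
        tot <- sum(a[cbind(seq_len(nr), p)])
        best <- if (maximize) max(best, tot) else min(best, tot)
      }
  } else {
    for (rows in utils::combn(nr, nc, simplify = FALSE))
      for (p in perms(rows)) {
        tot <- sum(a[cbind(p, seq_len(nc))])
        best <- if (maximize) max(best, tot) else min(best, tot)
      }
  }
  best
}

# reference reimplementation of the greedy rule (sequential argmin/argmax)
oracle_greedy <- function(a, tau, maximize = FALSE) {
  claimed <- rep(FALSE, ncol(a))
  out <- NULL
  for (i in seq_len(nrow(a))) {
    bestj <- 0L; bestv <- if (maximize) -Inf else Inf
    for (j in seq_len(ncol(a))) {
      if (claimed[j]) next
      better <- if (maximize) a[i, j] > bestv else a[i, j] < bestv
      if (better) { bestv <- a[i, j]; bestj <- j }
    }
    if (bestj == 0L) next
    accept <- if (maximize) bestv >= tau else bestv <= tau
    if (accept) { claimed[bestj] <- TRUE; out <- rbind(out, c(i, bestj)) }
  }
  if (is.null(out)) matrix(integer(0L), ncol = 2L) else out
}

# --- geometry oracles -------------------------------------------------------

# ray-casting point-in-polygon (crossing number); points near edges are the
# caller's responsibility to avoid
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# 8-connected flood fill size from a seed pixel (row, col), binary matrix
oracle_flood_fill_size <- function(binary, seed) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(seed)
  count <- 0L
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- p[1L]; c <- p[2L]
    if (r < 1L || r > nr || c < 1L || c > nc) next
    if (seen[r, c] || binary[r, c] == 0) next
    seen[r, c] <- TRUE
    count <- count + 1L
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
  }
  count
}

# run-length intervals of TRUE stretches
oracle_true_runs <- function(flags) {
  out <- NULL
  start <- NA_integer_
  for (i in seq_along(flags)) {
    if (flags[i] && is.na(start)) start <- i
    if (!flags[i] && !is.na(start)) {
      out <- rbind(out, c(start, i - 1L)); start <- NA_integer_
    }
  }
  if (!is.na(start)) out <- rbind(out, c(start, length(flags)))
  if (is.null(out)) data.frame(start = integer(0L), end = integer(0L))
  else data.frame(start = out[, 1L], end = out[, 2L])
}

# --- fixture builders -------------------------------------------------------

# paint a filled disk into a matrix (1-based matrix indexing, 0-based coords)
paint_disk_fixture <- function(img, cx, cy, r, level = 200) {
  for (yy in max(0, floor(cy - r)):min(nrow(img) - 1, ceiling(cy + r)))
    for (xx in max(0, floor(cx - r)):min(ncol(img) - 1, ceiling(cx + r)))
      if ((xx - cx)^2 + (yy - cy)^2 <= r^2)
        img[yy + 1L, xx + 1L] <- max(img[yy + 1L, xx + 1L], level)
  img
}

# constant-width straight capsule image along a given direction
capsule_image <- function(len = 40, r = 5, angle_deg = 0, size = 100,
                          cx = size / 2, cy = size / 2, level = 200) {
  img <- matrix(0, size, size)
  th <- angle_deg * pi / 180
  for (s in seq(-len / 2, len / 2, by = 0.5))
    img <- paint_disk_fixture(img, cx + s * cos(th), cy + s * sin(th), r, level)
  img
}

# single contour of an image (stops if segmentation finds != 1)
single_contour <- function(img) {
  cts <- find_contours(img)
  stopifnot(length(cts) == 1L)
  cts[[1L]]
}

# analytic closed contour (e.g. circle/ellipse) as an lt_contour; the pixel
# set is a coarse rasterization, sufficient for area-independent operations
analytic_contour <- function(pts) {
  pix <- unique(round(pts))
  lt_contour(pts, pix)
}

ellipse_points <- function(a, b, n = 100, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

# minimal posture model with prescribed landmarks; the contour is a thin
# rectangle around the midline so coil ratios stay far from the circular limit
fake_model <- function(head, tail, n_spine = 5L, width = 6) {
  head <- as.numeric(head); tail <- as.numeric(tail)
  ax <- tail - head
  len <- sqrt(sum(ax^2))
  u <- ax / len
  nvec <- c(-u[2L], u[1L]) * width / 2
  poly <- rbind(head + nvec, tail + nvec, tail - nvec, head - nvec)
  fr <- seq(0, 1, length.out = n_spine + 2L)[2:(n_spine + 1L)]
  spine <- cbind(head[1L] + fr * ax[1L], head[2L] + fr * ax[2L])
  pix <- unique(round(rbind(poly, spine, (head + tail) / 2)))
  structure(list(head = head, tail = tail, spine = spine,
                 radii = rep(width / 2, n_spine),
                 com = (head + tail) / 2,
                 area = nrow(pix), perimeter = 2 * (len + width),
                 contour = lt_contour(poly, pix)),
            class = "lt_model")
}

# --- cached scenario runs ---------------------------------------------------
# expensive rendered-pipeline runs shared across test files (computed once
# per session)

.lt_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .lt_test_cache))
    assign(key, force(expr), envir = .lt_test_cache)
  get(key, envir = .lt_test_cache)
}

seg_synth <- function() seg_config(gray_threshold = 40, area_min = 100,
                                   area_max = 1000)

forward_run <- function() cached("forward", {
  out <- render_scene(scenario("forward_crawl", seed = 1))
  tracks <- track_sequence(out$frames, seg = seg_synth())
  list(scene = out, tracks = tracks,
       report = match_and_deviate(tracks, out$truth))
})

headcast_run <- function() cached("headcast", {
  out <- render_scene(scenario("headcast", seed = 2))
  tracks <- track_sequence(out$frames, seg = seg_synth())
  list(scene = out, tracks = tracks,
       report = match_and_deviate(tracks, out$truth))
})

rolling_scene <- function() cached("rolling", render_scene(scenario("rolling", seed = 3)))

coiling_run <- function() cached("coiling", {
  out <- render_scene(scenario("coiling", seed = 5))
  tracks <- track_sequence(out$frames, seg = seg_synth())
  list(scene = out, tracks = tracks)
})
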