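# Synthetic dark-field scenes with exact per-frame ground truth.
#
# Emulates FTIR-style recordings: near-black background, bright
# capsule-shaped animals, optional static artifact blobs and additive
# Gaussian noise.  Each animal follows a parametric midline whose
# per-frame head, spine points, radii, tail and center of mass are known
# analytically before rasterization, so every tracking stage can be
# validated without external data.

#' Specification of one synthetic animal
#'
#' Kinematics: the anchor point advances along the heading by `speed`
#' px/frame (optionally modulated by a peristalsis factor), the heading
#' turns by `turn_deg` per frame, and the body bends by `bend_deg`
#' (total tangent rotation from tail to head along the midline).
#' `bend_shape` `"arc"` spreads the bend uniformly (constant curvature);
#' `"head"` bends only the head-side half (head casting) with the tail
#' anchored.  `lateral` displaces the anchor perpendicular to the
#' heading each frame (simulated rolling).
#'
#' @param x0,y0 initial anchor position (px).
#' @param heading_deg initial heading (degrees; 0 = +x, measured toward
#'   +y, i.e. clockwise on screen).
#' @param length body length (px), `width` maximal body diameter (px).
#' @param speed px/frame (scalar or per-frame vector).
#' @param turn_deg degrees/frame (scalar or per-frame vector).
#' @param bend_deg degrees (scalar or per-frame vector).
#' @param bend_shape `"arc"` or `"head"`.
#' @param anchor `"center"` (anchor = body midpoint) or `"tail"`.
#' @param lateral px/frame perpendicular displacement (scalar or vector).
#' @param peristalsis_amp,peristalsis_period relative speed modulation
#'   amplitude and its period in frames (0 disables).
#' @return list describing the animal.
#' @export
synthetic_animal <- function(x0, y0, heading_deg = 0, length = 40, width = 10,
                             speed = 1.5, turn_deg = 0, bend_deg = 0,
                             bend_shape = c("arc", "head"),
                             anchor = c("center", "tail"), lateral = 0,
                             peristalsis_amp = 0, peristalsis_period = 8) {
  list(x0 = x0, y0 = y0, heading_deg = heading_deg, length = length,
       width = width, speed = speed, turn_deg = turn_deg,
       bend_deg = bend_deg, bend_shape = match.arg(bend_shape),
       anchor = match.arg(anchor), lateral = lateral,
       peristalsis_amp = peristalsis_amp,
       peristalsis_period = peristalsis_period)
}

#' Specification of a synthetic scene
#'
#' @param width,height image dimensions (px).
#' @param frames number of frames.
#' @param animals list of [synthetic_animal()] specs.
#' @param fps nominal frame rate (metadata for feature configs).
#' @param bg_level background intensity, `body_level` animal intensity
#'   (0-255); their difference must exceed the planned segmentation
#'   threshold.
#' @param noise_sd additive Gaussian noise standard deviation (clipped
#'   to [0, 255]).
#' @param artifacts list of static bright blobs, each
#'   `list(x =, y =, r =, level =)`; they appear in every frame and are
#'   therefore captured by the minimum background.
#' @param coil_truth_deg bend magnitude (degrees) above which a frame is
#'   labeled coiled in the ground truth.
#' @param seed RNG seed making the rendering deterministic.
#' @return object of class `lt_scene`.
#' @export
scene_spec <- function(width = 256, height = 256, frames = 50,
                       animals = list(), fps = 10, bg_level = 10,
                       body_level = 200, noise_sd = 0, artifacts = list(),
                       coil_truth_deg = 270, seed = 1L) {
  stopifnot(width > 0, height > 0, frames >= 1, body_level > bg_level)
  structure(list(width = width, height = height, frames = frames,
                 animals = animals, fps = fps, bg_level = bg_level,
                 body_level = body_level, noise_sd = noise_sd,
                 artifacts = artifacts, coil_truth_deg = coil_truth_deg,
                 seed = as.integer(seed)),
            class = "lt_scene")
}

per_frame <- function(x, n) if (length(x) == 1L) rep(x, n) else {
  stopifnot(length(x) == n); x
}

#' Body half-width profile of synthetic animals
#'
#' Constant over the central half of the body, half-cosine taper over
#' the terminal 25% of the length at each end.  The head end tapers to a
#' smaller tip than the tail end, so the sharpest contour curvature
#' marks the head by construction; radii are floored at 0.8 px so the
#' rasterized body stays connected.
#'
#' @param u arc-length fraction in [0, 1]; 0 = tail tip, 1 = head tip.
#' @param r_max maximal half-width (px).
#' @param head_tip,tail_tip tip half-widths as fractions of `r_max`.
#' @return vector of half-widths (px).
#' @export
radius_profile <- function(u, r_max, head_tip = 0.25, tail_tip = 0.45) {
  f <- rep(1, length(u))
  lo <- u < 0.25
  f[lo] <- tail_tip + (1 - tail_tip) * (1 - cos(pi * u[lo] / 0.25)) / 2
  hi <- u > 0.75
  f[hi] <- head_tip + (1 - head_tip) * (1 - cos(pi * (1 - u[hi]) / 0.25)) / 2
  pmax(r_max * f, 0.8)
}

# midline sample positions for one animal at one frame.
# Returns list(pts = n x 2 (tail -> head), u, r)
animal_midline <- function(an, anchor_pos, heading_rad, bend_rad, ds = 0.5) {
  len <- an$length
  s <- seq(0, len, by = ds)
  if (s[length(s)] < len) s <- c(s, len)
  u <- s / len
  g <- switch(an$bend_shape,
              arc = u - 0.5,
              head = pmax(0, u - 0.5))
  phi <- heading_rad + bend_rad * g
  # integrate tangent from the tail (trapezoid on the fine grid)
  dx <- cos(phi); dy <- sin(phi)
  step <- diff(s)
  x <- c(0, cumsum((dx[-1L] + dx[-length(dx)]) / 2 * step))
  y <- c(0, cumsum((dy[-1L] + dy[-length(dy)]) / 2 * step))
  pts <- cbind(x, y)
  ref <- switch(an$anchor,
                tail = pts[1L, ],
                center = pts[which.min(abs(s - len / 2)), ])
  pts <- pts + matrix(anchor_pos - ref, nrow(pts), 2L, byrow = TRUE)
  list(pts = pts, u = u, r = radius_profile(u, an$width / 2), s = s)
}

# interpolate a point on the sampled midline at arc position `at`
midline_point <- function(ml, at) {
  c(stats::approx(ml$s, ml$pts[, 1L], xout = at, ties = "ordered")$y,
    stats::approx(ml$s, ml$pts[, 2L], xout = at, ties = "ordered")$y)
}

paint_disk <- function(img, cx, cy, r, level) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0L, floor(cx - r)); x1 <- min(nc - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(nr - 1L, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  mask <- outer(dy2, dx2, `+`) <= r^2
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[mask] <- pmax(sub[mask], level)
  img[ys + 1L, xs + 1L] <- sub
  img
}

#' Render a synthetic scene
#'
#' Draws every animal as the union of filled disks centered on its
#' midline with the local radius (a tapered capsule), adds static
#' artifacts and noise, and returns the frames together with the exact
#' ground truth derived from the midline before rasterization.
#'
#' @param spec [scene_spec()].
#' @param n_spine_points number of ground-truth midline landmarks L
#'   (head + interior points + tail; default 7, i.e. 5 interior points).
#' @return list with `frames` (list of intensity matrices), `truth`
#'   (data.frame: `frame`, `id`, `head_x/y`, `spine<k>_x/y` and
#'   `radius<k>` for the interior points ordered from the head side,
#'   `tail_x/y`, `mom_x/y`, `bending` (degrees), `coiled`, `phase`) and
#'   `background` (the noise-free scene without animals: background
#'   level plus static artifacts).
#' @export
render_scene <- function(spec, n_spine_points = 7L) {
  set.seed(spec$seed)
  Tn <- spec$frames
  K <- n_spine_points - 2L
  truth <- NULL
  frames <- vector("list", Tn)
  # per-animal state
  states <- lapply(spec$animals, function(an)
    list(pos = c(an$x0, an$y0), heading = an$heading_deg * pi / 180))
  margin <- 25
  for (t in seq_len(Tn)) {
    img <- matrix(spec$bg_level, spec$height, spec$width)
    for (art in spec$artifacts)
      img <- paint_disk(img, art$x, art$y, art$r, art$level)
    for (i in seq_along(spec$animals)) {
      an <- spec$animals[[i]]
      st <- states[[i]]
      speed <- per_frame(an$speed, Tn)[t]
      if (an$peristalsis_amp > 0)
        speed <- speed * (1 + an$peristalsis_amp *
                            sin(2 * pi * t / an$peristalsis_period))
      turn <- per_frame(an$turn_deg, Tn)[t] * pi / 180
      bend <- per_frame(an$bend_deg, Tn)[t] * pi / 180
      lateral <- per_frame(an$lateral, Tn)[t]
      if (t > 1L) {
        st$heading <- st$heading + turn
        # steer away from the walls to keep the body inside the frame
        nxt <- st$pos + speed * c(cos(st$heading), sin(st$heading))
        if (nxt[1L] < margin || nxt[1L] > spec$width - margin ||
            nxt[2L] < margin || nxt[2L] > spec$height - margin) {
          to_center <- atan2(spec$height / 2 - st$pos[2L],
                             spec$width / 2 - st$pos[1L])
          d <- atan2(sin(to_center - st$heading), cos(to_center - st$heading))
          st$heading <- st$heading + sign(d) * min(abs(d), 8 * pi / 180)
        }
        st$pos <- st$pos + speed * c(cos(st$heading), sin(st$heading))
        if (lateral != 0) {
          perp <- c(-sin(st$heading), cos(st$heading))
          cand <- st$pos + lateral * perp
          if (cand[1L] < margin || cand[1L] > spec$width - margin ||
              cand[2L] < margin || cand[2L] > spec$height - margin)
            cand <- st$pos - lateral * perp
          st$pos <- cand
        }
      }
      states[[i]] <- st
      ml <- animal_midline(an, st$pos, st$heading, bend)
      for (k in seq_len(nrow(ml$pts)))
        img <- paint_disk(img, ml$pts[k, 1L], ml$pts[k, 2L], ml$r[k],
                          spec$body_level)
      # analytic ground truth from the midline
      len <- an$length
      head_p <- ml$pts[nrow(ml$pts), ]
      tail_p <- ml$pts[1L, ]
      w <- ml$r                                   # area weight ~ 2 r ds
      com <- c(sum(ml$pts[, 1L] * w), sum(ml$pts[, 2L] * w)) / sum(w)
      rec <- data.frame(frame = t, id = i,
                        head_x = head_p[1L], head_y = head_p[2L])
      for (k in seq_len(K)) {
        at <- len * (1 - k / (K + 1L))            # spine1 on the head side
        sp <- midline_point(ml, at)
        rec[[paste0("spine", k, "_x")]] <- sp[1L]
        rec[[paste0("spine", k, "_y")]] <- sp[2L]
        rec[[paste0("radius", k)]] <- radius_profile(at / len, an$width / 2)
      }
      rec$tail_x <- tail_p[1L]; rec$tail_y <- tail_p[2L]
      rec$mom_x <- com[1L]; rec$mom_y <- com[2L]
      mid <- midline_point(ml, len / 2)
      rec$bending <- bending_angle(head_p, mid, tail_p)
      rec$coiled <- abs(per_frame(an$bend_deg, Tn)[t]) >= spec$coil_truth_deg
      rec$phase <- if (speed > 1 &&
                       abs(per_frame(an$bend_deg, Tn)[t]) < 30) "go" else "reorient"
      truth <- rbind(truth, rec)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    frames[[t]] <- round(pmin(pmax(img, 0), 255))
  }
  empty <- matrix(spec$bg_level, spec$height, spec$width)
  for (art in spec$artifacts)
    empty <- paint_disk(empty, art$x, art$y, art$r, art$level)
  list(frames = frames, truth = truth, background = empty)
}

#' Named scenario library
#'
#' Ready-made scene specifications exercising the locomotion regimes the
#' tracker must handle: `forward_crawl` (five peristaltically crawling
#' animals), `rolling` (large per-frame lateral displacement, no
#' consecutive-frame contour overlap), `snake` (sinusoidal undulation),
#' `collision` (two animals merging and separating), `coiling` (a curl
#' episode), `headcast` (stationary head sweeps with the tail anchored).
#'
#' @param name scenario name (see above).
#' @param seed RNG seed for the rendering.
#' @param frames optional override of the scenario's frame count.
#' @return [scene_spec()].
#' @export
scenario <- function(name = c("forward_crawl", "rolling", "snake",
                              "collision", "coiling", "headcast"),
                     seed = 1L, frames = NULL) {
  name <- match.arg(name)
  sp <- switch(name,
    forward_crawl = {
      n <- 200
      # each animal crawls on its own circular orbit (constant gentle turn
      # rate); centers are spaced so that the five paths never intersect
      centers <- list(c(128, 128), c(384, 128), c(128, 384), c(384, 384),
                      c(256, 256))
      r_orbit <- 60
      animals <- lapply(seq_along(centers), function(i) {
        ctr <- centers[[i]]
        phi <- 2 * pi * (i - 1) / 5
        synthetic_animal(ctr[1L] + r_orbit * cos(phi),
                         ctr[2L] + r_orbit * sin(phi),
                         heading_deg = phi * 180 / pi + 90,
                         length = 40, width = 10, speed = 1.5,
                         turn_deg = 1.43 + 0.3 * sin(2 * pi * seq_len(n) / 60 + i),
                         bend_deg = 15 * sin(2 * pi * seq_len(n) / 30 + 2 * i),
                         peristalsis_amp = 0.2, peristalsis_period = 8)
      })
      scene_spec(width = 512, height = 512, frames = n, animals = animals,
                 noise_sd = 3,
                 artifacts = list(list(x = 200, y = 300, r = 4, level = 90),
                                  list(x = 350, y = 180, r = 3, level = 80),
                                  list(x = 120, y = 250, r = 5, level = 70)),
                 seed = seed)
    },
    rolling = {
      n <- 25
      animals <- list(
        synthetic_animal(60, 60, heading_deg = 0, length = 30, width = 8,
                         speed = 0.5, lateral = 25),
        synthetic_animal(190, 190, heading_deg = 180, length = 30, width = 8,
                         speed = 0.5, lateral = 25))
      scene_spec(width = 256, height = 256, frames = n, animals = animals,
                 noise_sd = 2, seed = seed)
    },
    snake = {
      n <- 100
      scene_spec(width = 320, height = 320, frames = n,
                 animals = list(synthetic_animal(
                   70, 160, heading_deg = 0, length = 36, width = 6,
                   speed = 2,
                   turn_deg = 8 * sin(2 * pi * seq_len(n) / 20),
                   bend_deg = 60 * sin(2 * pi * seq_len(n) / 20))),
                 noise_sd = 2, seed = seed)
    },
    collision = {
      n <- 80
      scene_spec(width = 256, height = 256, frames = n,
                 animals = list(
                   synthetic_animal(50, 124, heading_deg = 0, length = 35,
                                    width = 9, speed = 1.8),
                   synthetic_animal(206, 132, heading_deg = 180, length = 35,
                                    width = 9, speed = 1.8)),
                 noise_sd = 2, seed = seed)
    },
    coiling = {
      n <- 100
      bend <- c(rep(0, 30), seq(0, 330, length.out = 25), rep(330, 20),
                seq(330, 0, length.out = 25))
      scene_spec(width = 256, height = 256, frames = n,
                 animals = list(synthetic_animal(
                   128, 128, heading_deg = 20, length = 40, width = 9,
                   speed = 0.3, bend_deg = bend)),
                 noise_sd = 2, seed = seed)
    },
    headcast = {
      n <- 150
      scene_spec(width = 256, height = 256, frames = n,
                 animals = list(synthetic_animal(
                   100, 128, heading_deg = 0, length = 40, width = 10,
                   speed = 0.35,   # slow reorientation crawl; the minimum
                                   # background needs > 1 body length of travel
                   bend_deg = 45 * sin(2 * pi * seq_len(n) / 40),
                   bend_shape = "head", anchor = "tail")),
                 noise_sd = 2, seed = seed)
    })
  if (!is.null(frames)) {
    sp$frames <- frames
    # truncate/recycle per-frame schedules
    sp$animals <- lapply(sp$animals, function(an) {
      for (f in c("speed", "turn_deg", "bend_deg", "lateral"))
        if (length(an[[f]]) > 1L)
          an[[f]] <- rep_len(an[[f]], frames)
      an
    })
  }
  sp
}

#' Ground-truth row as point landmarks
#'
#' Convenience accessor turning one row of the `truth` table into the
#' head/spine/tail/center-of-mass landmark set used by the evaluator.
#'
#' @param row single-row data.frame from `render_scene()$truth`.
#' @return list with `head`, `spine` (K x 2 matrix), `tail`, `com`,
#'   `bending`.
#' @export
truth_landmarks <- function(row) {
  k <- 1L
  spine <- NULL
  while (!is.null(row[[paste0("spine", k, "_x")]])) {
    spine <- rbind(spine, c(row[[paste0("spine", k, "_x")]],
                            row[[paste0("spine", k, "_y")]]))
    k <- k + 1L
  }
  list(head = c(row$head_x, row$head_y), spine = spine,
       tail = c(row$tail_x, row$tail_y), com = c(row$mom_x, row$mom_y),
       bending = row$bending)
}
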