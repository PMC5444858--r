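# Posture, motion and phase features per animal per frame.
#
# Features that are undefined (sequence boundaries of the velocity
# window, spine-derived quantities on coiled frames, degenerate
# geometry) are emitted as NA, never silently as 0.

#' Feature-computation parameters
#'
#' @param fps frame rate in frames per second; the velocity uses a
#'   central window of one second, i.e. floor(fps / 2) frames to each
#'   side (fps must be at least 2).
#' @param bend_threshold_deg tau_bend: minimal deviation of the bending
#'   angle from 180 degrees to call a left/right sweep, and the
#'   straightness bound of the go-phase classifier.
#' @param go_velocity_threshold minimal center-of-mass speed (px/frame)
#'   for a go-phase frame.
#' @param go_min_frames tau_go: minimal run length (frames) of raw
#'   go-frames to count as a go phase.
#' @param coil_perimeter_tol relative tolerance on |P / S_l - pi| for
#'   the coil test (a coiled body's perimeter-to-spine-length ratio
#'   approaches pi).
#' @param coil_radius_tol tolerance on |2 * r_mid * pi / P - 1| (a
#'   coiled body approaches the circle with the mid-spine radius).
#' @param acceleration_divisor divisor of the absolute velocity
#'   difference (default 2).
#' @return object of class `lt_feature_config`.
#' @export
feature_config <- function(fps = 10, bend_threshold_deg = 20,
                           go_velocity_threshold = 1, go_min_frames = 5L,
                           coil_perimeter_tol = 0.1, coil_radius_tol = 0.15,
                           acceleration_divisor = 2) {
  stopifnot(fps >= 2, bend_threshold_deg >= 0, go_min_frames >= 1L,
            go_velocity_threshold >= 0, coil_perimeter_tol > 0,
            coil_radius_tol > 0, acceleration_divisor > 0)
  structure(list(fps = fps, bend_threshold_deg = bend_threshold_deg,
                 go_velocity_threshold = go_velocity_threshold,
                 go_min_frames = as.integer(go_min_frames),
                 coil_perimeter_tol = coil_perimeter_tol,
                 coil_radius_tol = coil_radius_tol,
                 acceleration_divisor = acceleration_divisor),
            class = "lt_feature_config")
}

#' Signed body bending angle
#'
#' Angle gamma at the mid-spine point between the head-side vector
#' v1 = h - s_mid and the tail-side vector v2 = s_mid - t.  A straight
#' body gives gamma = 180 degrees; the magnitude of the deviation from
#' 180 is the unsigned angle arccos(<v1, v2> / (|v1| |v2|)).  The side
#' comes from the 2-D cross product of v2 and v1 in image coordinates
#' (y pointing down): positive cross = left bend (gamma > 180), negative
#' = right bend (gamma < 180).
#'
#' @param h,s_mid,t (x, y) points: head, mid-spine point, tail.
#' @return gamma in degrees, in (0, 360); NA if either vector degenerates
#'   to zero length.
#' @export
bending_angle <- function(h, s_mid, t) {
  v1 <- h - s_mid
  v2 <- s_mid - t
  n1 <- vnorm(v1); n2 <- vnorm(v2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  dev <- acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  cross <- v2[1L] * v1[2L] - v2[2L] * v1[1L]
  180 + sign(cross) * dev
}

#' Classify a bending angle as a left/right sweep or straight
#'
#' @param gamma bending angle in degrees.
#' @param bend_threshold tau_bend in degrees.
#' @return `"left"` if gamma >= 180 + tau_bend, `"right"` if
#'   gamma <= 180 - tau_bend, otherwise `"straight"`; NA for NA input.
#' @export
sweep_state <- function(gamma, bend_threshold) {
  if (is.na(gamma)) return(NA_character_)
  if (gamma >= 180 + bend_threshold) "left"
  else if (gamma <= 180 - bend_threshold) "right"
  else "straight"
}

#' Spine length of a model
#'
#' Sum of Euclidean distances along head, interior spine points, tail.
#'
#' @param model [lt_model()].
#' @return length in px.
#' @export
spine_length <- function(model) {
  polyline_length(rbind(model$head, model$spine, model$tail, deparse.level = 0))
}

#' Coiled-posture indicator
#'
#' When the body curls onto itself the midline cannot be recovered from
#' the outer contour, and two ratios betray it: the perimeter over the
#' spine length approaches pi, and the circumference of the circle with
#' the mid-spine radius approaches the perimeter.  The indicator fires
#' if either ratio is within its tolerance of the circular limit.
#'
#' @param model [lt_model()].
#' @param config [feature_config()].
#' @return logical.
#' @export
is_coiled <- function(model, config = feature_config()) {
  sl <- spine_length(model)
  p <- model$perimeter
  if (sl <= 0 || p <= 0) return(TRUE)
  r_mid <- model$radii[mid_spine_index(model)]
  abs(p / sl - pi) <= config$coil_perimeter_tol * pi ||
    abs(2 * r_mid * pi / p - 1) <= config$coil_radius_tol
}

#' Accumulated path distance of a center-of-mass series
#'
#' @param com T x 2 matrix of per-frame centers of mass.
#' @return vector d_acc of length T; d_acc[t] is the summed step length
#'   up to frame t (0 at t = 1).
#' @export
accumulated_distance <- function(com) {
  n <- nrow(com)
  if (n == 1L) return(0)
  steps <- sqrt(rowSums((com[-1L, , drop = FALSE] - com[-n, , drop = FALSE])^2))
  c(0, cumsum(steps))
}

#' Distance to the trajectory origin
#'
#' @param com T x 2 matrix of per-frame centers of mass.
#' @return vector d_org of length T; d_org[t] = |m_1 - m_t| (0 at t = 1).
#' @export
distance_to_origin <- function(com) {
  sqrt(rowSums((com - matrix(com[1L, ], nrow(com), 2L, byrow = TRUE))^2))
}

#' Center-of-mass velocity over a one-second central window
#'
#' v_m(t) = |m_(t - h) - m_(t + h)| / fps with h = floor(fps / 2).
#' Frames whose window leaves the series get NA.
#'
#' @param com T x 2 matrix.
#' @param fps frame rate (frames per second, >= 2).
#' @return vector of length T in px/frame (divide by the frame duration,
#'   i.e. multiply by fps, for px/s).
#' @export
velocity <- function(com, fps) {
  stopifnot(fps >= 2)
  h <- floor(fps / 2)
  n <- nrow(com)
  v <- rep(NA_real_, n)
  t <- seq_len(n)
  ok <- t - h >= 1 & t + h <= n
  if (any(ok)) {
    d <- sqrt(rowSums((com[t[ok] - h, , drop = FALSE] -
                       com[t[ok] + h, , drop = FALSE])^2))
    v[ok] <- d / fps
  }
  v
}

#' Acceleration from consecutive velocities
#'
#' a_m(t) = |v_m(t) - v_m(t + 1)| / divisor; NA wherever either velocity
#' is undefined (the last frame always is).
#'
#' @param vel velocity series from [velocity()].
#' @param divisor see [feature_config()] (`acceleration_divisor`).
#' @return vector of the same length in px/frame^2.
#' @export
acceleration <- function(vel, divisor = 2) {
  n <- length(vel)
  a <- rep(NA_real_, n)
  if (n >= 2L)
    a[seq_len(n - 1L)] <- abs(vel[-n] - vel[-1L]) / divisor
  a
}

#' Go-phase classification
#'
#' A frame is a raw go-frame when the velocity exceeds the threshold and
#' the body is nearly straight (|gamma - 180| < tau_bend).  A frame
#' belongs to a go phase only if it sits in a run of at least
#' `go_min_frames` consecutive raw go-frames; everything else is
#' reorientation.
#'
#' @param vel velocity series (NA allowed).
#' @param gamma bending-angle series (NA allowed).
#' @param config [feature_config()].
#' @return list with `go` (logical vector; NA-velocity frames are FALSE)
#'   and `phases` (data.frame with columns `start`, `end`, one row per
#'   go phase).
#' @export
go_phases <- function(vel, gamma, config = feature_config()) {
  stopifnot(length(vel) == length(gamma))
  raw <- !is.na(vel) & vel > config$go_velocity_threshold &
    !is.na(gamma) & abs(gamma - 180) < config$bend_threshold_deg
  r <- rle(raw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$go_min_frames
  go <- rep(FALSE, length(raw))
  for (k in which(keep)) go[starts[k]:ends[k]] <- TRUE
  list(go = go,
       phases = data.frame(start = starts[keep], end = ends[keep]))
}

#' Per-frame feature table for one trajectory
#'
#' Computes the full feature record series: area, perimeter, bending
#' angle with sweep indicators, spine length, coiled indicator,
#' accumulated distance, distance to origin, velocity, acceleration,
#' go-phase indicator, and (optionally) distance / bearing / region
#' indicator for each stimulus marker.  Bending-derived columns are NA
#' on coiled frames.
#'
#' @param traj `lt_trajectory` object.
#' @param config [feature_config()].
#' @param markers optional list of stimulus markers (see
#'   [stim_point()] and friends).
#' @return data.frame with one row per frame, 1-based `frame` indices.
#' @export
trajectory_features <- function(traj, config = feature_config(), markers = NULL) {
  models <- traj$models
  n <- length(models)
  com <- t(vapply(models, `[[`, numeric(2L), "com"))
  gamma <- vapply(models, function(m)
    bending_angle(m$head, mid_spine_point(m), m$tail), numeric(1L))
  coiled <- vapply(models, is_coiled, logical(1L), config = config)
  gamma[coiled] <- NA_real_
  sweep <- vapply(gamma, sweep_state, character(1L),
                  bend_threshold = config$bend_threshold_deg)
  vel <- velocity(com, config$fps)
  acc <- acceleration(vel, config$acceleration_divisor)
  gp <- go_phases(vel, gamma, config)
  out <- data.frame(
    animal_id = traj$id,
    frame = trajectory_frames(traj),
    mom_x = com[, 1L], mom_y = com[, 2L],
    area = vapply(models, `[[`, numeric(1L), "area"),
    perimeter = vapply(models, `[[`, numeric(1L), "perimeter"),
    bending = gamma,
    left_bended = ifelse(is.na(sweep), NA, sweep == "left"),
    right_bended = ifelse(is.na(sweep), NA, sweep == "right"),
    spine_length = vapply(models, spine_length, numeric(1L)),
    coiled = coiled,
    acc_distance = accumulated_distance(com),
    dist_origin = distance_to_origin(com),
    velocity = vel,
    acceleration = acc,
    go_phase = gp$go
  )
  for (mk in markers) {
    dist <- numeric(n); bear <- numeric(n); inside <- logical(n)
    for (t in seq_len(n)) {
      m <- models[[t]]
      dist[t] <- stimulus_distance(mk, m$com)
      bear[t] <- bearing_angle(m$com, m$tail, nearest_point(mk, m$com))
      inside[t] <- in_region(mk, m$com)
    }
    out[[paste0("dist_to_", mk$id)]] <- dist
    out[[paste0("bearing_", mk$id)]] <- bear
    out[[paste0("in_", mk$id)]] <- inside
  }
  out
}

#' Feature table for all trajectories
#'
#' @param tracks `lt_tracks` object from [track_models()] /
#'   [track_sequence()].
#' @param config [feature_config()].
#' @param markers optional list of stimulus markers.
#' @return data.frame, trajectories stacked.
#' @export
features_table <- function(tracks, config = feature_config(), markers = NULL) {
  out <- do.call(rbind, lapply(tracks, trajectory_features,
                               config = config, markers = markers))
  if (is.null(out))
    out <- data.frame(animal_id = integer(0L), frame = integer(0L))
  out
}
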