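# Trajectory-level head/tail correction.
#
# Per-frame curvature can swap head and tail (non-rigid body wall, low
# per-animal resolution, organisms with unusual curvature profiles).
# Orientation is therefore decided over whole uncoiled stretches of a
# trajectory from two motion cues, then landmark identity is stabilized
# frame to frame by nearest-predecessor anchoring.

#' Maximal uncoiled runs of a trajectory
#'
#' @param coiled_flags logical vector aligned with the trajectory's
#'   frames (TRUE = coiled, spine unreliable).
#' @return data.frame with columns `start`, `end`: 1-based positions
#'   (relative to the trajectory) of the maximal runs with
#'   coiled = FALSE.
#' @export
uncoiled_segments <- function(coiled_flags) {
  r <- rle(!coiled_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Orientation vote for a stretch of models
#'
#' Estimates the probability that the current head label is correct from
#' two cues: locomotion conformity (the mid-point-to-head vector points
#' in the direction the center of mass moves) and bending conformity
#' (during slow, reorienting frames the head endpoint moves more than
#' the tail endpoint, since these animals cast the head while the tail
#' stays put).  Each cue contributes the fraction of frame pairs that
#' agree with the current labels; the combined probability is the mean
#' of the cues that had any evidence.
#'
#' @param models list of [lt_model()] for consecutive frames.
#' @param config [feature_config()]; its `go_velocity_threshold`
#'   separates the slow frames used by the bending cue.
#' @param min_step minimal center-of-mass displacement (px) for a frame
#'   pair to count as locomotion evidence.
#' @return list with `locomotion_score`, `bending_score`, `combined`
#'   (all in [0, 1]; cues without evidence are NA, combined falls back
#'   to the neutral 0.5 when no cue has evidence or the stretch is
#'   shorter than 2 frames).
#' @export
orientation_probability <- function(models, config = feature_config(),
                                    min_step = 1e-9) {
  n <- length(models)
  neutral <- list(locomotion_score = NA_real_, bending_score = NA_real_,
                  combined = 0.5)
  if (n < 2L) return(neutral)
  loco_hits <- 0L; loco_n <- 0L
  bend_hits <- 0L; bend_n <- 0L
  for (t in seq_len(n - 1L)) {
    a <- models[[t]]; b <- models[[t + 1L]]
    step <- b$com - a$com
    speed <- vnorm(step)
    if (speed > min_step) {
      forward <- a$head - mid_spine_point(a)
      loco_n <- loco_n + 1L
      if (sum(forward * step) > 0) loco_hits <- loco_hits + 1L
    }
    if (speed <= config$go_velocity_threshold) {
      dh <- pdist(b$head, a$head)
      dt <- pdist(b$tail, a$tail)
      if (dh != dt) {
        bend_n <- bend_n + 1L
        if (dh > dt) bend_hits <- bend_hits + 1L
      }
    }
  }
  loco <- if (loco_n > 0L) loco_hits / loco_n else NA_real_
  bend <- if (bend_n > 0L) bend_hits / bend_n else NA_real_
  scores <- c(loco, bend)
  combined <- if (all(is.na(scores))) 0.5 else mean(scores, na.rm = TRUE)
  list(locomotion_score = loco, bending_score = bend, combined = combined)
}

flip_model <- function(m) {
  k <- nrow(m$spine)
  lt_model(head = m$tail, tail = m$head,
           spine = m$spine[rev(seq_len(k)), , drop = FALSE],
           radii = rev(m$radii), com = m$com, contour = m$contour)
}

#' Swap head and tail over given frame intervals
#'
#' Within each interval the head and tail labels are exchanged and the
#' spine points and radii reversed; contour-derived fields (center of
#' mass, area, perimeter) are untouched.  Spine-derived features must be
#' recomputed afterwards ([trajectory_features()] always computes from
#' the current landmark order).
#'
#' @param traj `lt_trajectory` object.
#' @param flip_intervals data.frame with columns `start`, `end`
#'   (positions relative to the trajectory).
#' @return the corrected trajectory.
#' @export
apply_orientation <- function(traj, flip_intervals) {
  n <- length(traj$models)
  for (k in seq_len(nrow(flip_intervals))) {
    s <- flip_intervals$start[k]; e <- flip_intervals$end[k]
    stopifnot(s >= 1L, e <= n, s <= e)
    for (t in s:e) traj$models[[t]] <- flip_model(traj$models[[t]])
  }
  traj
}

#' Stabilize head/tail identity by nearest-predecessor anchoring
#'
#' After the orientation of the first frame is trusted, each subsequent
#' frame assigns the head label to whichever of its two endpoints is
#' nearer to the previous frame's head; the tail gets the other.  This
#' removes isolated per-frame curvature-based switches.
#'
#' @param traj `lt_trajectory` object.
#' @return the corrected trajectory.
#' @export
anchor_landmarks <- function(traj) {
  n <- length(traj$models)
  if (n < 2L) return(traj)
  for (t in 2L:n) {
    prev_head <- traj$models[[t - 1L]]$head
    cur <- traj$models[[t]]
    if (pdist(cur$head, prev_head) > pdist(cur$tail, prev_head))
      traj$models[[t]] <- flip_model(cur)
  }
  traj
}

#' Head/tail correction for one trajectory
#'
#' First makes the landmark identity consistent across the trajectory by
#' nearest-predecessor anchoring (per-frame curvature labels can
#' alternate), then determines the maximal uncoiled stretches, votes on
#' the orientation of each sufficiently long stretch and flips it when
#' the vote says the labels are more likely swapped (combined
#' probability below the flip threshold); coiled frames inherit the
#' decision of the preceding stretch (the leading ones that of the first
#' stretch).  A final anchoring pass stabilizes the result.
#'
#' @param traj `lt_trajectory` object.
#' @param config [feature_config()].
#' @param min_segment minimal stretch length to vote on (shorter
#'   stretches keep their labels and are resolved by the anchoring).
#' @param flip_threshold flip when the combined probability falls below
#'   this value (default 0.5).
#' @return the corrected trajectory.
#' @export
correct_trajectory <- function(traj, config = feature_config(),
                               min_segment = 2L, flip_threshold = 0.5) {
  n <- length(traj$models)
  # make the per-frame curvature-based labels consistent before voting:
  # an orientation probability is only meaningful over a stretch whose
  # labels do not alternate frame to frame
  traj <- anchor_landmarks(traj)
  coiled <- vapply(traj$models, is_coiled, logical(1L), config = config)
  segs <- uncoiled_segments(coiled)
  if (nrow(segs) == 0L) return(traj)
  # extend each stretch to cover the coiled frames that follow it (and the
  # first stretch to cover leading coiled frames), so every frame inherits
  # one decision
  cover_start <- segs$start
  cover_end <- segs$end
  cover_start[1L] <- 1L
  if (nrow(segs) > 1L)
    cover_start[-1L] <- cover_end[-nrow(segs)] + 1L
  cover_end[nrow(segs)] <- n
  if (nrow(segs) > 1L)
    cover_end[-nrow(segs)] <- cover_start[-1L] - 1L
  flips <- NULL
  for (k in seq_len(nrow(segs))) {
    if (segs$end[k] - segs$start[k] + 1L < min_segment) next
    vote <- orientation_probability(traj$models[segs$start[k]:segs$end[k]],
                                    config = config)
    if (vote$combined < flip_threshold)
      flips <- rbind(flips, data.frame(start = cover_start[k],
                                       end = cover_end[k]))
  }
  if (!is.null(flips)) traj <- apply_orientation(traj, flips)
  anchor_landmarks(traj)
}

#' Head/tail correction for all trajectories
#'
#' Applies [correct_trajectory()] independently to every trajectory (no
#' cross-animal information is used).  Idempotent: a second run changes
#' nothing.
#'
#' @param tracks `lt_tracks` object.
#' @param config [feature_config()].
#' @param min_segment,flip_threshold see [correct_trajectory()].
#' @return corrected `lt_tracks` object.
#' @export
correct_head_tail <- function(tracks, config = feature_config(),
                              min_segment = 2L, flip_threshold = 0.5) {
  out <- lapply(tracks, correct_trajectory, config = config,
                min_segment = min_segment, flip_threshold = flip_threshold)
  attributes(out) <- attributes(tracks)
  out
}
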