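# Frame-to-frame association of posture models into trajectories.

#' Tracking parameters
#'
#' @param cost_method one of `"com"` (Euclidean distance between centers
#'   of mass), `"mid"` (distance between middle spine points) or
#'   `"overlap"` (intersecting area in pixels of the two contours; a
#'   similarity, higher is better).
#' @param solver `"hungarian"` (optimal bipartite matching with an
#'   inside-contour validation of every accepted pair) or `"greedy"`
#'   (sequential best-match with an acceptance threshold).
#' @param greedy_threshold for the greedy solver: maximal accepted
#'   distance (px) for distance costs, or minimal required overlap (px^2)
#'   for overlap costs.
#' @return object of class `lt_track_config`.
#' @export
track_config <- function(cost_method = c("overlap", "com", "mid"),
                         solver = c("hungarian", "greedy"),
                         greedy_threshold = 30) {
  cost_method <- match.arg(cost_method)
  solver <- match.arg(solver)
  if (solver == "greedy") stopifnot(greedy_threshold > 0)
  structure(list(cost_method = cost_method, solver = solver,
                 greedy_threshold = greedy_threshold),
            class = "lt_track_config")
}

# index of the middle spine point: ceiling(K/2), ties to the lower index
mid_spine_index <- function(model) as.integer(ceiling(nrow(model$spine) / 2))

#' Middle spine point of a model
#' @param model [lt_model()].
#' @return (x, y) point.
#' @export
mid_spine_point <- function(model) model$spine[mid_spine_index(model), ]

#' Pixel overlap of two contours
#'
#' Number of pixels enclosed by both contours (exact, from the stored
#' component pixel sets).
#'
#' @param a,b [lt_contour()] objects.
#' @return non-negative integer count.
#' @export
contour_overlap <- function(a, b) {
  length(intersect(pixel_keys(a$pixels), pixel_keys(b$pixels)))
}

#' Assignment cost between two models
#'
#' @param a,b [lt_model()] objects from consecutive frames.
#' @param method see [track_config()].
#' @return scalar: a distance in px for `"com"`/`"mid"`, an overlap area
#'   in px^2 for `"overlap"` (similarity: higher is better).
#' @export
pairwise_cost <- function(a, b, method = c("com", "mid", "overlap")) {
  method <- match.arg(method)
  switch(method,
         com = pdist(a$com, b$com),
         mid = pdist(mid_spine_point(a), mid_spine_point(b)),
         overlap = contour_overlap(a$contour, b$contour))
}

#' Cost matrix between two frames' model sets
#'
#' @param models_a,models_b lists of [lt_model()] (frames t and t + 1).
#' @param method see [track_config()].
#' @return N_t x N_{t+1} matrix with attribute `method`.
#' @export
cost_matrix <- function(models_a, models_b, method = c("com", "mid", "overlap")) {
  method <- match.arg(method)
  m <- matrix(0, nrow = length(models_a), ncol = length(models_b))
  for (i in seq_along(models_a))
    for (j in seq_along(models_b))
      m[i, j] <- pairwise_cost(models_a[[i]], models_b[[j]], method)
  attr(m, "method") <- method
  m
}

#' Optimal bipartite assignment
#'
#' Hungarian matching of min(N_t, N_{t+1}) pairs.  Rectangular matrices
#' are padded with a large sentinel cost; sentinel pairs are discarded
#' from the result.  Overlap (similarity) matrices are negated
#' internally so that the maximal total overlap is found.
#'
#' @param costs numeric matrix (rows = frame t, columns = frame t + 1).
#' @param maximize treat entries as similarities and maximize the total.
#' @return integer matrix with columns `i`, `j`, one row per matched pair.
#' @export
solve_hungarian <- function(costs, maximize = FALSE) {
  nr <- nrow(costs); nc <- ncol(costs)
  if (nr == 0L || nc == 0L)
    return(matrix(integer(0L), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  a <- if (maximize) -costs else costs
  n <- max(nr, nc)
  sentinel <- max(a[is.finite(a)], 0) + 1e6
  sq <- matrix(sentinel, n, n)
  sq[seq_len(nr), seq_len(nc)] <- a
  col <- lsap_min_square(sq)
  pairs <- cbind(i = seq_len(n), j = col)
  pairs <- pairs[pairs[, "i"] <= nr & pairs[, "j"] <= nc, , drop = FALSE]
  pairs
}

#' Inside-contour validation of an assignment
#'
#' Accepts a matched pair only if at least one landmark of the earlier
#' model (head, spine points, tail, center of mass) lies inside or on
#' the later model's contour; otherwise the earlier trajectory must
#' terminate and the later detection spawns a new identity.
#'
#' @param a [lt_model()] at frame t.
#' @param b [lt_model()] at frame t + 1.
#' @return logical.
#' @export
validate_assignment <- function(a, b) {
  pts <- model_points(a)
  any(points_in_polygon(pts[, 1L], pts[, 2L], b$contour$points))
}

#' Greedy sequential assignment with an acceptance threshold
#'
#' Rows are visited in ascending index order; each takes its best
#' unclaimed column (minimum distance or maximum overlap, ties broken by
#' the lower column index).  A pair is accepted only if its distance is
#' at most `greedy_threshold` (distance costs) or its overlap at least
#' `greedy_threshold` (overlap costs).
#'
#' @param costs numeric matrix with attribute `method` (as produced by
#'   [cost_matrix()]), or pass `method` explicitly.
#' @param config [track_config()] providing `greedy_threshold`.
#' @param method cost method; defaults to the matrix attribute.
#' @return integer matrix with columns `i`, `j`.
#' @export
solve_greedy <- function(costs, config, method = attr(costs, "method")) {
  stopifnot(!is.null(method))
  maximize <- identical(method, "overlap")
  tau <- config$greedy_threshold
  claimed <- rep(FALSE, ncol(costs))
  out <- NULL
  for (i in seq_len(nrow(costs))) {
    if (all(claimed)) break
    row <- costs[i, ]
    row[claimed] <- if (maximize) -Inf else Inf
    j <- if (maximize) which.max(row) else which.min(row)  # ties -> lower j
    ok <- if (maximize) row[j] >= tau else row[j] <= tau
    if (length(j) == 1L && is.finite(row[j]) && ok) {
      claimed[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(integer(0L), ncol = 2L)
  colnames(out) <- c("i", "j")
  out
}

new_trajectory <- function(id, start_frame, model) {
  structure(list(id = id, start = start_frame, models = list(model),
                 active = TRUE),
            class = "lt_trajectory")
}

#' @export
print.lt_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %d: frames %d-%d (%d models)%s>\n", x$id, x$start,
              x$start + length(x$models) - 1L, length(x$models),
              if (x$active) "" else ", terminated"))
  invisible(x)
}

#' Frames covered by a trajectory (1-based, contiguous)
#' @param traj [lt_trajectory] object.
#' @return integer vector.
#' @export
trajectory_frames <- function(traj) seq(traj$start, length.out = length(traj$models))

# one association step; returns updated trajectory list
step_assign <- function(trajectories, models_next, frame_next, config, id_counter) {
  active_idx <- which(vapply(trajectories, `[[`, logical(1L), "active"))
  prev_models <- lapply(trajectories[active_idx], function(tr) tr$models[[length(tr$models)]])
  maximize <- config$cost_method == "overlap"
  matched_traj <- integer(0L)
  matched_model <- integer(0L)
  if (length(prev_models) > 0L && length(models_next) > 0L) {
    costs <- cost_matrix(prev_models, models_next, config$cost_method)
    pairs <- if (config$solver == "hungarian")
      solve_hungarian(costs, maximize = maximize)
    else
      solve_greedy(costs, config)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, "i"]; j <- pairs[k, "j"]
      ok <- if (config$solver == "hungarian") {
        if (maximize) costs[i, j] > 0
        else validate_assignment(prev_models[[i]], models_next[[j]])
      } else TRUE                       # greedy already applied its threshold
      if (ok) {
        matched_traj <- c(matched_traj, active_idx[i])
        matched_model <- c(matched_model, j)
      }
    }
  }
  for (k in seq_along(matched_traj)) {
    ti <- matched_traj[k]
    trajectories[[ti]]$models[[length(trajectories[[ti]]$models) + 1L]] <-
      models_next[[matched_model[k]]]
  }
  for (ti in setdiff(active_idx, matched_traj))
    trajectories[[ti]]$active <- FALSE
  for (j in setdiff(seq_along(models_next), matched_model)) {
    id_counter <- id_counter + 1L
    trajectories[[length(trajectories) + 1L]] <-
      new_trajectory(id_counter, frame_next, models_next[[j]])
  }
  list(trajectories = trajectories, id_counter = id_counter)
}

#' Track a sequence of per-frame model sets
#'
#' Core association loop, separated from segmentation so that tests and
#' synthetic pipelines can feed models directly.  Identities come from a
#' monotonically increasing counter and are never reused or merged; a
#' trajectory that fails assignment terminates and the unmatched
#' detection spawns a new identity.
#'
#' @param models_by_frame list (one element per frame) of lists of
#'   [lt_model()].
#' @param config [track_config()].
#' @return object of class `lt_tracks`: list of `lt_trajectory`, with
#'   attribute `n_frames`.
#' @export
track_models <- function(models_by_frame, config = track_config()) {
  stopifnot(length(models_by_frame) >= 1L)
  trajectories <- list()
  id_counter <- 0L
  for (m in models_by_frame[[1L]]) {
    id_counter <- id_counter + 1L
    trajectories[[id_counter]] <- new_trajectory(id_counter, 1L, m)
  }
  for (t in seq_along(models_by_frame)[-1L]) {
    st <- step_assign(trajectories, models_by_frame[[t]], t, config, id_counter)
    trajectories <- st$trajectories
    id_counter <- st$id_counter
  }
  structure(trajectories, class = "lt_tracks", n_frames = length(models_by_frame))
}

#' @export
print.lt_tracks <- function(x, ...) {
  cat(sprintf("<%d trajectories over %d frames>\n", length(x), attr(x, "n_frames")))
  invisible(x)
}

#' Full tracking pipeline on an image sequence
#'
#' Background estimation, per-frame segmentation and model extraction,
#' frame-to-frame association, and trajectory-level head/tail
#' correction.
#'
#' @param frames list of intensity matrices.
#' @param seg [seg_config()].
#' @param model [model_config()].
#' @param track [track_config()].
#' @param features [feature_config()] (used by the head/tail correction
#'   and downstream feature computation).
#' @param postprocess run trajectory-level head/tail correction
#'   (default TRUE).
#' @param background optional precomputed background matrix.
#' @param background_stride passed to [compute_background()].
#' @param verbose print per-frame detection/termination/spawn counts.
#' @return `lt_tracks` object (see [track_models()]).
#' @export
track_sequence <- function(frames, seg = seg_config(), model = model_config(),
                           track = track_config(), features = feature_config(),
                           postprocess = TRUE, background = NULL,
                           background_stride = 1L, verbose = FALSE) {
  check_frame_stack(frames)
  if (is.null(background))
    background <- compute_background(frames, stride = background_stride)
  models_by_frame <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    fg <- extract_foreground(frames[[t]], background, seg)
    contours <- filter_contours(find_contours(fg), seg)
    models_by_frame[[t]] <- build_models(contours, model)
    if (verbose)
      message(sprintf("frame %d: %d animals", t, length(models_by_frame[[t]])))
  }
  tracks <- track_models(models_by_frame, track)
  if (postprocess)
    tracks <- correct_head_tail(tracks, config = features)
  tracks
}
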