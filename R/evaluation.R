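# Deviation of tracking results from ground truth: center of mass,
# central spine point, and body bending, summarized with and without
# outliers.

summarize_dev <- function(x, outlier_k = 1.5) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(data.frame(mean = NA_real_, sd = NA_real_, median = NA_real_,
                      min = NA_real_, max = NA_real_, max_star = NA_real_,
                      n_outliers = 0L, outlier_frac = 0, n = 0L))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  out <- x < q[1L] - outlier_k * iqr | x > q[2L] + outlier_k * iqr
  kept <- x[!out]
  if (length(kept) == 0L) kept <- x
  data.frame(mean = mean(kept), sd = stats::sd(kept),
             median = stats::median(kept), min = min(kept), max = max(kept),
             max_star = max(x), n_outliers = sum(out),
             outlier_frac = sum(out) / length(x), n = length(x))
}

# circular difference of two angles in degrees, in [0, 180]
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Deviation report of tracked trajectories against ground truth
#'
#' Matches each trajectory to a ground-truth identity by majority vote
#' over per-frame nearest centers of mass, then computes per frame the
#' Euclidean deviations of the center of mass and of the central spine
#' point, and the absolute bending-angle difference.  The bending
#' difference is the minimal circular difference unless the frame is
#' flagged as a head/tail swap (tracked head closer to the true tail
#' than to the true head), in which case the raw difference is kept so
#' that swaps surface in the maxima.
#'
#' Only trajectories spanning at least `min_coverage` of the ground
#' truth frames enter the statistics; ground-truth animals without such
#' a match are reported as lost.
#'
#' @param tracks `lt_tracks` object.
#' @param truth ground-truth data.frame from [render_scene()].
#' @param outlier_k Tukey-fence multiplier for the outlier rule
#'   (values beyond `outlier_k` * IQR from the quartiles are outliers;
#'   summary `max` excludes them, `max_star` includes them).
#' @param min_coverage minimal fraction of the ground-truth frame range
#'   a trajectory must span to be evaluated (default 1 = fully tracked
#'   trajectories only).
#' @return object of class `lt_deviation_report`: list with `per_frame`
#'   (data.frame: trajectory id, truth id, frame, `dev_com`, `dev_mid`,
#'   `dev_bending`, `head_swapped`, `head_correct`), `summary` (one row
#'   per measure), `per_animal` (summaries by truth id), `lost`
#'   (unmatched truth ids), `n_switches` (frames where a trajectory's
#'   nearest truth identity differs from its majority identity).
#' @export
match_and_deviate <- function(tracks, truth, outlier_k = 1.5,
                              min_coverage = 1) {
  t_frames <- sort(unique(truth$frame))
  n_frames <- length(t_frames)
  per <- NULL
  n_switches <- 0L
  matched_ids <- integer(0L)
  for (tr in tracks) {
    frames <- trajectory_frames(tr)
    frames <- frames[frames %in% t_frames]
    if (length(frames) < min_coverage * n_frames) next
    # nearest truth identity per frame
    near <- integer(length(frames))
    for (k in seq_along(frames)) {
      f <- frames[k]
      m <- tr$models[[f - tr$start + 1L]]
      cand <- truth[truth$frame == f, ]
      d <- sqrt((cand$mom_x - m$com[1L])^2 + (cand$mom_y - m$com[2L])^2)
      near[k] <- cand$id[which.min(d)]
    }
    truth_id <- as.integer(names(which.max(table(near))))
    n_switches <- n_switches + sum(near != truth_id)
    matched_ids <- c(matched_ids, truth_id)
    for (k in seq_along(frames)) {
      f <- frames[k]
      m <- tr$models[[f - tr$start + 1L]]
      row <- truth[truth$frame == f & truth$id == truth_id, ]
      gt <- truth_landmarks(row)
      gt_mid <- gt$spine[ceiling(nrow(gt$spine) / 2), ]
      g_tr <- bending_angle(m$head, mid_spine_point(m), m$tail)
      swapped <- pdist(m$head, gt$head) > pdist(m$head, gt$tail)
      dev_b <- if (is.na(g_tr) || is.na(gt$bending)) NA_real_
               else if (swapped) abs(g_tr - gt$bending)
               else circ_diff(g_tr, gt$bending)
      per <- rbind(per, data.frame(
        trajectory = tr$id, truth_id = truth_id, frame = f,
        dev_com = pdist(m$com, gt$com),
        dev_mid = pdist(mid_spine_point(m), gt_mid),
        dev_bending = dev_b,
        head_swapped = swapped,
        head_correct = !swapped,
        coiled_truth = isTRUE(row$coiled)))
    }
  }
  lost <- setdiff(unique(truth$id), matched_ids)
  if (is.null(per)) {
    summary <- NULL; per_animal <- NULL
  } else {
    mk <- function(col) summarize_dev(per[[col]], outlier_k)
    summary <- cbind(measure = c("center_of_mass", "central_spine_point",
                                 "body_bending"),
                     rbind(mk("dev_com"), mk("dev_mid"), mk("dev_bending")))
    per_animal <- do.call(rbind, lapply(split(per, per$truth_id), function(d)
      cbind(truth_id = d$truth_id[1L],
            measure = c("center_of_mass", "central_spine_point",
                        "body_bending"),
            rbind(summarize_dev(d$dev_com, outlier_k),
                  summarize_dev(d$dev_mid, outlier_k),
                  summarize_dev(d$dev_bending, outlier_k)))))
    rownames(per_animal) <- NULL
  }
  structure(list(per_frame = per, summary = summary, per_animal = per_animal,
                 lost = lost, n_switches = n_switches),
            class = "lt_deviation_report")
}

#' @export
print.lt_deviation_report <- function(x, ...) {
  cat("Deviation report\n")
  if (!is.null(x$summary)) {
    print(x$summary, row.names = FALSE, digits = 3)
  } else cat("  (no evaluable trajectories)\n")
  if (length(x$lost)) cat("lost ground-truth animals:",
                          paste(x$lost, collapse = ", "), "\n")
  cat("identity switches:", x$n_switches, "\n")
  invisible(x)
}

#' Write a deviation report as CSV files
#'
#' Emits `<prefix>_summary.csv` (pooled), `<prefix>_per_animal.csv` and
#' `<prefix>_per_frame.csv`.
#'
#' @param report `lt_deviation_report`.
#' @param prefix output path prefix.
#' @return invisibly, the written file names.
#' @export
write_deviation_report <- function(report, prefix) {
  files <- character(0L)
  for (part in c("summary", "per_animal", "per_frame")) {
    d <- report[[part]]
    if (is.null(d)) next
    f <- paste0(prefix, "_", part, ".csv")
    utils::write.csv(d, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
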