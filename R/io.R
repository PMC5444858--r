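# Readers, writers and run configuration.
#
# Input: a directory of TIFF or PNG frames, lexicographic file order =
# temporal order, 8-bit grayscale (16-bit accepted with rescaling).
# Output: long- and wide-format CSV feature tables and a trajectory
# overlay image.  CSV dialect: comma separator, '.' decimal, UTF-8, LF;
# undefined features are empty fields.

read_one_image <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lower)) {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("unreadable file: ", path,
                                             " (", conditionMessage(e), ")"))
    if (max(img) > 255) {
      warning("16-bit image rescaled to 8-bit: ", path)
      img <- img / 257
    }
  } else if (grepl("\\.png$", lower)) {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable file: ", path,
                                             " (", conditionMessage(e), ")"))
    img <- img * 255
  } else stop("unsupported image format: ", path)
  if (length(dim(img)) == 3L) {
    warning("multi-channel image converted to grayscale by channel mean: ", path)
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  round(img)
}

#' Read an image sequence from a directory
#'
#' TIFF and PNG frames, one file per frame, ordered lexicographically.
#'
#' @param path directory containing the frames.
#' @param invert invert intensities (255 - I) for transmitted-light
#'   recordings where animals are dark on bright background.
#' @return list of intensity matrices.
#' @export
read_sequence <- function(path, invert = FALSE) {
  stopifnot(dir.exists(path))
  files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF or PNG frames in ", path)
  frames <- lapply(files, read_one_image)
  check_frame_stack(frames)
  if (invert) frames <- lapply(frames, function(f) 255 - f)
  frames
}

#' Write an image sequence as PNG (or TIFF) files
#'
#' @param frames list of intensity matrices (0-255).
#' @param path output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @param prefix file-name prefix; frames are numbered `%04d`.
#' @return invisibly, the written file names.
#' @export
write_sequence <- function(frames, path, format = c("png", "tiff"),
                           prefix = "frame") {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(frames))
  for (t in seq_along(frames)) {
    f <- file.path(path, sprintf("%s%04d.%s", prefix, t,
                                 if (format == "png") "png" else "tif"))
    m <- pmin(pmax(frames[[t]] / 255, 0), 1)
    if (format == "png") png::writePNG(m, f)
    else tiff::writeTIFF(m, f, bits.per.sample = 8L)
    files[t] <- f
  }
  invisible(files)
}

#' Long-format feature table
#'
#' One record per (animal, frame, feature); undefined values are kept as
#' NA and written as empty CSV fields.
#'
#' @param features wide per-frame data.frame from [features_table()].
#' @return data.frame with columns `animal_id`, `frame`, `feature`,
#'   `value`.
#' @export
features_long <- function(features) {
  cols <- setdiff(names(features), c("animal_id", "frame"))
  if (length(cols) == 0L || nrow(features) == 0L)
    return(data.frame(animal_id = integer(0L), frame = integer(0L),
                      feature = character(0L), value = numeric(0L)))
  out <- do.call(rbind, lapply(cols, function(cn)
    data.frame(animal_id = features$animal_id, frame = features$frame,
               feature = cn, value = as.numeric(features[[cn]]))))
  out[order(out$animal_id, out$frame, out$feature), , drop = FALSE]
}

#' Wide per-animal feature table
#'
#' Mirrors the table view of the original interface: animals in columns,
#' (feature, frame) combinations in rows.
#'
#' @param features wide per-frame data.frame from [features_table()].
#' @return data.frame with columns `feature`, `frame`, then one column
#'   `animal_<id>` per animal.
#' @export
features_wide <- function(features) {
  long <- features_long(features)
  ids <- sort(unique(long$animal_id))
  key <- unique(long[, c("feature", "frame")])
  key <- key[order(key$feature, key$frame), , drop = FALSE]
  out <- key
  for (id in ids) {
    sub <- long[long$animal_id == id, ]
    out[[paste0("animal_", id)]] <-
      sub$value[match(paste(key$feature, key$frame),
                      paste(sub$feature, sub$frame))]
  }
  rownames(out) <- NULL
  out
}

#' Landmark table of tracked models
#'
#' One row per trajectory per frame with the full posture model (head,
#' interior spine points with radii, tail, center of mass) — the same
#' schema as the ground-truth table of [render_scene()], with the
#' trajectory identity in `id`.
#'
#' @param tracks `lt_tracks` object.
#' @return data.frame.
#' @export
tracks_table <- function(tracks) {
  out <- NULL
  for (tr in tracks) {
    frames <- trajectory_frames(tr)
    for (k in seq_along(frames)) {
      m <- tr$models[[k]]
      rec <- data.frame(frame = frames[k], id = tr$id,
                        head_x = m$head[1L], head_y = m$head[2L])
      for (j in seq_len(nrow(m$spine))) {
        rec[[paste0("spine", j, "_x")]] <- m$spine[j, 1L]
        rec[[paste0("spine", j, "_y")]] <- m$spine[j, 2L]
        rec[[paste0("radius", j)]] <- m$radii[j]
      }
      rec$tail_x <- m$tail[1L]; rec$tail_y <- m$tail[2L]
      rec$mom_x <- m$com[1L]; rec$mom_y <- m$com[2L]
      rec$area <- m$area; rec$perimeter <- m$perimeter
      out <- rbind(out, rec)
    }
  }
  out
}

#' Rebuild trajectories from a landmark table
#'
#' Inverse of [tracks_table()] (up to the source contours, which a CSV
#' cannot carry): reconstructs the per-frame posture models so that a
#' written result can be re-evaluated against ground truth.
#'
#' @param df data.frame in the [tracks_table()] schema.
#' @return `lt_tracks` object (models lack contours; operations needing
#'   them, such as overlap costs, are unavailable).
#' @export
tracks_from_table <- function(df) {
  stopifnot(all(c("frame", "id", "head_x", "tail_x", "mom_x") %in% names(df)))
  ks <- grep("^spine[0-9]+_x$", names(df))
  K <- length(ks)
  trajs <- list()
  for (id in sort(unique(df$id))) {
    sub <- df[df$id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    models <- lapply(seq_len(nrow(sub)), function(r) {
      row <- sub[r, ]
      spine <- matrix(NA_real_, K, 2L)
      radii <- rep(1, K)
      for (j in seq_len(K)) {
        spine[j, ] <- c(row[[paste0("spine", j, "_x")]],
                        row[[paste0("spine", j, "_y")]])
        rj <- row[[paste0("radius", j)]]
        if (!is.null(rj)) radii[j] <- rj
      }
      structure(list(head = c(row$head_x, row$head_y),
                     tail = c(row$tail_x, row$tail_y),
                     spine = spine, radii = radii,
                     com = c(row$mom_x, row$mom_y),
                     area = if (is.null(row$area)) NA_real_ else row$area,
                     perimeter = if (is.null(row$perimeter)) NA_real_
                                 else row$perimeter,
                     contour = NULL),
                class = "lt_model")
    })
    trajs[[length(trajs) + 1L]] <-
      structure(list(id = id, start = sub$frame[1L], models = models,
                     active = FALSE),
                class = "lt_trajectory")
  }
  structure(trajs, class = "lt_tracks",
            n_frames = if (nrow(df)) max(df$frame) else 0L)
}

# deterministic color palette by identity
id_palette <- function(ids) {
  h <- (ids * 47) %% 360
  grDevices::hsv(h / 360, s = 0.9, v = 1)
}

#' Trajectory overlay image
#'
#' The last frame in grayscale with each trajectory's center-of-mass
#' path drawn in a deterministic per-identity color.
#'
#' @param tracks `lt_tracks` object.
#' @param frame background intensity matrix (typically the last frame).
#' @return H x W x 3 RGB array in [0, 1].
#' @export
trajectory_overlay <- function(tracks, frame) {
  g <- pmin(pmax(frame / 255, 0), 1)
  rgb <- array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
  for (tr in tracks) {
    col <- grDevices::col2rgb(id_palette(tr$id))[, 1L] / 255
    com <- t(vapply(tr$models, `[[`, numeric(2L), "com"))
    # draw each step as interpolated pixels
    for (k in seq_len(nrow(com) - 1L)) {
      n <- max(2L, ceiling(pdist(com[k, ], com[k + 1L, ])) + 1L)
      xs <- round(seq(com[k, 1L], com[k + 1L, 1L], length.out = n))
      ys <- round(seq(com[k, 2L], com[k + 1L, 2L], length.out = n))
      ok <- xs >= 0 & xs < ncol(g) & ys >= 0 & ys < nrow(g)
      for (ch in 1:3)
        rgb[cbind(ys[ok] + 1L, xs[ok] + 1L, ch)] <- col[ch]
    }
    if (nrow(com) == 1L) {
      xs <- round(com[1L, 1L]); ys <- round(com[1L, 2L])
      if (xs >= 0 && xs < ncol(g) && ys >= 0 && ys < nrow(g))
        for (ch in 1:3) rgb[ys + 1L, xs + 1L, ch] <- col[ch]
    }
  }
  rgb
}

#' Write tracking results
#'
#' Emits `features_long.csv`, `features_wide.csv`, `models.csv` (the
#' landmark table, see [tracks_table()]) and `trajectories.png` (overlay
#' of the center-of-mass paths on the last frame) into `path`.
#'
#' @param tracks `lt_tracks` object.
#' @param features wide per-frame data.frame from [features_table()].
#' @param path output directory (created if missing).
#' @param last_frame intensity matrix for the overlay background
#'   (optional; overlay is skipped when NULL).
#' @return invisibly, the written file names.
#' @export
write_results <- function(tracks, features, path, last_frame = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f_long <- file.path(path, "features_long.csv")
  f_wide <- file.path(path, "features_wide.csv")
  f_models <- file.path(path, "models.csv")
  utils::write.csv(features_long(features), f_long, row.names = FALSE,
                   na = "")
  utils::write.csv(features_wide(features), f_wide, row.names = FALSE,
                   na = "")
  utils::write.csv(tracks_table(tracks), f_models, row.names = FALSE, na = "")
  files <- c(f_long, f_wide, f_models)
  if (!is.null(last_frame)) {
    f_img <- file.path(path, "trajectories.png")
    png::writePNG(trajectory_overlay(tracks, last_frame), f_img)
    files <- c(files, f_img)
  }
  invisible(files)
}

#' Read a run configuration file
#'
#' Flat YAML key/value file; recognized keys are the configuration
#' parameters of [seg_config()], [model_config()], [track_config()] and
#' [feature_config()], plus a `markers` list (each entry: `kind`, `id`
#' and the shape parameters of [stim_point()] and friends).  Missing
#' keys fall back to the package defaults.
#'
#' @param path YAML file.
#' @return list with elements `seg`, `model`, `track`, `features`,
#'   `markers`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(fun, keys) {
    args <- raw[intersect(keys, names(raw))]
    do.call(fun, args)
  }
  markers <- lapply(raw$markers, function(mk) {
    switch(mk$kind,
           point = stim_point(mk$id, mk$x, mk$y),
           line = stim_line(mk$id, mk$x1, mk$y1, mk$x2, mk$y2),
           rectangle = stim_rect(mk$id, mk$xmin, mk$ymin, mk$xmax, mk$ymax),
           ellipse = stim_ellipse(mk$id, mk$cx, mk$cy, mk$a, mk$b),
           stop("unknown marker kind: ", mk$kind))
  })
  list(
    seg = pick(seg_config, c("gray_threshold", "area_min", "area_max")),
    model = pick(model_config, c("n_spine_points", "curvature_window",
                                 "head_tail_min_separation_frac",
                                 "d_min", "d_max")),
    track = pick(track_config, c("cost_method", "solver", "greedy_threshold")),
    features = pick(feature_config, c("fps", "bend_threshold_deg",
                                      "go_velocity_threshold", "go_min_frames",
                                      "coil_perimeter_tol", "coil_radius_tol",
                                      "acceleration_divisor")),
    markers = markers)
}

#' Run the full pipeline on an input directory
#'
#' Convenience wrapper used by the command-line interface: reads the
#' frames, tracks, computes features and writes the result files.
#'
#' @param input directory of TIFF/PNG frames.
#' @param out output directory.
#' @param config optional YAML configuration file (see
#'   [read_run_config()]).
#' @param invert invert intensities before tracking.
#' @param verbose log per-frame counts.
#' @return invisibly, a list with `tracks` and `features`.
#' @export
run_tracking <- function(input, out, config = NULL, invert = FALSE,
                         verbose = FALSE) {
  cfg <- read_run_config(config)
  frames <- read_sequence(input, invert = invert)
  tracks <- track_sequence(frames, seg = cfg$seg, model = cfg$model,
                           track = cfg$track, features = cfg$features,
                           verbose = verbose)
  feats <- features_table(tracks, config = cfg$features, markers = cfg$markers)
  write_results(tracks, feats, out, last_frame = frames[[length(frames)]])
  invisible(list(tracks = tracks, features = feats))
}
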