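# Curvature estimation, head/tail location, contour splitting and the
# assembled posture model.

test_that("curvature angles match geometry on squares and circles", {
  # big axis-aligned square: corners sharp (~90 deg), edge midpoints flat
  side <- 40
  xs <- 0:(side - 1)
  pts <- rbind(cbind(xs, 0), cbind(side - 1, xs), cbind(rev(xs), side - 1),
               cbind(0, rev(xs)))
  ct <- analytic_contour(pts)
  cfg <- model_config(d_min = 5L, d_max = 5L)
  curv <- contour_curvature(ct, cfg)
  # d_min/d_max rescale by n/100 = 1.6 -> arms of 8 points, well within a side
  corner_idx <- c(1L, side + 1L, 2L * side + 1L, 3L * side + 1L)
  mid_idx <- corner_idx + as.integer(side / 2)
  expect_true(all(curv[corner_idx] < 100))
  expect_true(all(abs(curv[mid_idx] - 180) < 1e-6))

  # analytic circle with exactly 100 points: rescaling is the identity and
  # the inscribed-angle closed form gives 180 - d_max * 360 / n
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- analytic_contour(cbind(30 * cos(th), 30 * sin(th)))
  cfg <- model_config(d_min = 4L, d_max = 7L)
  curv <- contour_curvature(circ, cfg)
  expected <- 180 - 7 * 360 / 100
  expect_true(all(abs(curv - expected) < 1.5))
  expect_lt(diff(range(curv)), 1e-6)          # rotational symmetry

  expect_error(contour_curvature(analytic_contour(cbind(0:3, c(0, 1, 0, -1)))),
               "too short")
})

test_that("head and tail land on the capsule caps, rotation-invariant", {
  for (ang in c(0, 90)) {
    img <- capsule_image(len = 40, r = 5, angle_deg = ang)
    ct <- single_contour(img)
    curv <- contour_curvature(ct)
    ht <- locate_head_tail(ct, curv)
    p_h <- ct$points[ht["head"], ]
    p_t <- ct$points[ht["tail"], ]
    th <- ang * pi / 180
    cap1 <- c(50, 50) + 25 * c(cos(th), sin(th))
    cap2 <- c(50, 50) - 25 * c(cos(th), sin(th))
    d_h <- min(sqrt(sum((p_h - cap1)^2)), sqrt(sum((p_h - cap2)^2)))
    d_t <- min(sqrt(sum((p_t - cap1)^2)), sqrt(sum((p_t - cap2)^2)))
    expect_lt(d_h, 6); expect_lt(d_t, 6)
    # on opposite caps, not the same one
    expect_gt(sqrt(sum((p_h - p_t)^2)), 30)
  }
})

test_that("head/tail equal an exhaustive window scan on an ellipse", {
  pts <- ellipse_points(a = 30, b = 10, n = 120)
  ct <- analytic_contour(pts)
  cfg <- model_config()
  curv <- contour_curvature(ct, cfg)
  ht <- locate_head_tail(ct, curv, cfg)
  # brute-force scan: circular window means, min; then min at separation
  n <- length(curv)
  w <- cfg$curvature_window
  means <- vapply(seq_len(n), function(i) {
    idx <- ((i - 1 + (-w:w)) %% n) + 1
    mean(curv[idx])
  }, numeric(1))
  expect_equal(unname(ht["head"]), which.min(means))
  sep <- round(cfg$head_tail_min_separation_frac * n)
  dist <- pmin(abs(seq_len(n) - ht["head"]), n - abs(seq_len(n) - ht["head"]))
  cand <- which(dist >= sep)
  expect_equal(unname(ht["tail"]), cand[which.min(means[cand])])
  # both ends sit near the major-axis endpoints (within a small arc)
  expect_lt(abs(abs(ct$points[ht["head"], 1]) - 30), 3)
  expect_lt(abs(abs(ct$points[ht["tail"], 1]) - 30), 3)
})

test_that("split halves pair mirror points on a symmetric capsule", {
  img <- capsule_image(len = 40, r = 5, angle_deg = 0)
  ct <- single_contour(img)
  curv <- contour_curvature(ct)
  ht <- locate_head_tail(ct, curv)
  halves <- split_and_resample(ct, ht[["head"]], ht[["tail"]])
  expect_equal(nrow(halves$half1), nrow(halves$half2))
  expect_equal(halves$half1[1, ], halves$half2[1, ])       # both start at head
  k <- nrow(halves$half1)
  expect_equal(halves$half1[k, ], halves$half2[k, ])       # both end at tail
  # mirror symmetry about the capsule axis y = 50
  mids <- (halves$half1[, 2] + halves$half2[, 2]) / 2
  expect_true(all(abs(mids - 50) <= 1.5))
})

test_that("splitting handles adjacent endpoints and matches interpolation", {
  sq <- analytic_contour(cbind(c(0, 10, 10, 0, 0, 10), c(0, 0, 5, 5, 2, 2))[1:4, ])
  # adjacent head/tail: one chain has 2 points; the other resamples to 2
  halves <- split_and_resample(sq, 1L, 2L)
  expect_equal(nrow(halves$half1), 2L)
  expect_equal(halves$half2[1, ], sq$points[1, ])
  expect_equal(halves$half2[2, ], sq$points[2, ])

  # random convex contour: the longer chain is resampled to the shorter
  # length and matches a piecewise-linear interpolation oracle
  set.seed(21)
  th <- sort(runif(30, 0, 2 * pi))
  pts <- cbind(20 * cos(th), 12 * sin(th))
  ct <- analytic_contour(pts)
  halves <- split_and_resample(ct, 1L, 10L)
  expect_equal(nrow(halves$half1), 10L)
  expect_equal(nrow(halves$half2), 10L)
  long_chain <- pts[c(1, 30:10), ]                    # head -> tail, long way
  seg <- sqrt(rowSums(diff(long_chain)^2))
  cum <- c(0, cumsum(seg))
  tgt <- seq(0, sum(seg), length.out = 10)
  oracle <- cbind(approx(cum, long_chain[, 1], tgt)$y,
                  approx(cum, long_chain[, 2], tgt)$y)
  expect_equal(unname(halves$half2), unname(oracle), tolerance = 1e-8)
})

test_that("straight capsule model: spine on axis, radii near half-width", {
  img <- capsule_image(len = 40, r = 5, angle_deg = 0)
  m <- build_model(single_contour(img))
  expect_equal(nrow(m$spine), 5L)
  expect_true(all(abs(m$spine[, 2] - 50) <= 1))         # on the symmetry axis
  expect_true(all(abs(m$radii - 5) <= 1))
  expect_true(abs(median(m$radii) - 5) <= 1)
  expect_equal(m$com, unname(round(single_contour(img)$centroid)))
  # com within the bounding box of the contour
  expect_true(m$com[1] >= min(m$contour$points[, 1]) &&
              m$com[1] <= max(m$contour$points[, 1]))
})

test_that("spine stays within 2 px of the analytic midline on a bent body", {
  sp <- scene_spec(width = 200, height = 200, frames = 1,
                   animals = list(synthetic_animal(100, 100, heading_deg = 30,
                                                   bend_deg = 60, speed = 0)),
                   seed = 3)
  sc <- render_scene(sp)
  fg <- extract_foreground(sc$frames[[1]], sc$background, seg_config())
  m <- build_model(filter_contours(find_contours(fg), seg_synth())[[1]])
  gt <- truth_landmarks(sc$truth[1, ])
  midline <- rbind(gt$head, gt$spine, gt$tail)
  pt_seg <- function(p, a, b) {
    d <- b - a
    t <- min(max(sum((p - a) * d) / sum(d^2), 0), 1)
    sqrt(sum((a + t * d - p)^2))
  }
  devs <- apply(m$spine, 1, function(p)
    min(vapply(seq_len(nrow(midline) - 1), function(i)
      pt_seg(p, midline[i, ], midline[i + 1, ]), numeric(1))))
  expect_lt(max(devs), 2)
})

test_that("model extraction is equivariant under integer translation", {
  img <- capsule_image(len = 36, r = 5, angle_deg = 25, size = 120)
  ct <- single_contour(img)
  m1 <- build_model(ct)
  shift <- c(7, -4)
  ct2 <- lt_contour(sweep(ct$points, 2, shift, "+"),
                    sweep(ct$pixels, 2, shift, "+"))
  m2 <- build_model(ct2)
  expect_equal(m2$head, m1$head + shift)
  expect_equal(m2$tail, m1$tail + shift)
  expect_equal(unname(m2$spine), unname(sweep(m1$spine, 2, shift, "+")))
  expect_equal(m2$com, m1$com + shift)
  expect_equal(m2$radii, m1$radii)
})

test_that("spine points lie inside the contour; length bounded by perimeter", {
  set.seed(22)
  for (ang in c(0, 33, 70)) {
    img <- capsule_image(len = 38, r = 5, angle_deg = ang, size = 120)
    m <- build_model(single_contour(img))
    inside <- pracma::inpolygon(m$spine[, 1], m$spine[, 2],
                                m$contour$points[, 1], m$contour$points[, 2],
                                boundary = TRUE)
    expect_true(all(inside))
    expect_lt(spine_length(m), m$perimeter / 2 + 6)
  }
})
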