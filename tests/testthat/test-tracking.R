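# Cost measures, Hungarian and greedy solvers, assignment validation,
# and trajectory bookkeeping.

test_that("pairwise costs match identity, translation and brute force", {
  img <- capsule_image(len = 30, r = 4, angle_deg = 15, size = 80)
  a <- build_model(single_contour(img))
  expect_equal(pairwise_cost(a, a, "com"), 0)
  expect_equal(pairwise_cost(a, a, "mid"), 0)
  expect_equal(pairwise_cost(a, a, "overlap"), a$area)

  # 3-4-5 translation with disjoint 3x3 blobs
  img1 <- matrix(0, 20, 20); img1[2:4, 2:4] <- 200
  img2 <- matrix(0, 20, 20); img2[6:8, 5:7] <- 200   # shifted by (3, 4)
  c1 <- find_contours(img1)[[1]]; c2 <- find_contours(img2)[[1]]
  expect_equal(contour_overlap(c1, c2), 0)
  expect_equal(sqrt(sum((c1$centroid - c2$centroid)^2)), 5)

  expect_error(pairwise_cost(a, a, "bogus"))
})

test_that("contour overlap equals a brute-force pixel intersection", {
  set.seed(31)
  for (rep in 1:50) {
    img1 <- matrix(0, 30, 30); img2 <- matrix(0, 30, 30)
    for (k in 1:3) {
      img1 <- paint_disk_fixture(img1, runif(1, 8, 22), runif(1, 8, 22), runif(1, 2, 5))
      img2 <- paint_disk_fixture(img2, runif(1, 8, 22), runif(1, 8, 22), runif(1, 2, 5))
    }
    cts1 <- find_contours(img1); cts2 <- find_contours(img2)
    if (length(cts1) != 1L || length(cts2) != 1L) next
    got <- contour_overlap(cts1[[1]], cts2[[1]])
    expect_equal(got, sum(img1 > 0 & img2 > 0))
  }
})

test_that("Hungarian assignment is optimal (vs exhaustive enumeration)", {
  p <- solve_hungarian(matrix(5, 1, 1))
  expect_equal(unname(p), matrix(c(1L, 1L), 1))

  z <- matrix(1, 3, 3); z[1, 2] <- 0; z[2, 3] <- 0; z[3, 1] <- 0
  p <- solve_hungarian(z)
  expect_equal(p[order(p[, "i"]), "j"], c(2L, 3L, 1L), ignore_attr = TRUE)

  set.seed(32)
  for (rep in 1:200) {
    nr <- sample(1:7, 1); nc <- sample(1:7, 1)
    a <- matrix(round(runif(nr * nc, 0, 100), 2), nr, nc)
    p <- solve_hungarian(a)
    expect_equal(nrow(p), min(nr, nc))
    expect_equal(sum(a[p]), oracle_assignment_cost(a, maximize = FALSE))
    pm <- solve_hungarian(a, maximize = TRUE)
    expect_equal(sum(a[pm]), oracle_assignment_cost(a, maximize = TRUE))
  }
})

test_that("Hungarian is invariant to permutations and constant shifts", {
  set.seed(33)
  for (rep in 1:20) {
    a <- matrix(runif(36), 6, 6)
    base <- sum(a[solve_hungarian(a)])
    pr <- sample(6); pc <- sample(6)
    perm <- a[pr, pc]
    expect_equal(sum(perm[solve_hungarian(perm)]), base, tolerance = 1e-9)
    shifted <- a + 13.7
    expect_equal(sum(a[solve_hungarian(shifted)]), base, tolerance = 1e-9)
  }
})

test_that("inside-contour validation matches a ray-casting oracle", {
  img <- capsule_image(len = 30, r = 4, angle_deg = 0, size = 80)
  a <- build_model(single_contour(img))
  expect_true(validate_assignment(a, a))

  shift <- c(300, 0)   # ten body lengths away
  far <- lt_contour(sweep(a$contour$points, 2, shift, "+"),
                    sweep(a$contour$pixels, 2, shift, "+"))
  b_far <- build_model(far)
  expect_false(validate_assignment(a, b_far))

  # half-overlapping: per-point agreement with the independent oracle
  half <- lt_contour(sweep(a$contour$points, 2, c(15, 0), "+"),
                     sweep(a$contour$pixels, 2, c(15, 0), "+"))
  b_half <- build_model(half)
  pts <- model_points(a)
  oracle <- any(vapply(seq_len(nrow(pts)), function(i)
    oracle_in_polygon(pts[i, 1], pts[i, 2], b_half$contour$points), logical(1)))
  expect_equal(validate_assignment(a, b_half), oracle)
})

test_that("greedy matching follows the sequential threshold rule", {
  d <- matrix(10, 3, 3); diag(d) <- 1
  cfg <- track_config(cost_method = "com", solver = "greedy", greedy_threshold = 5)
  p <- solve_greedy(d, cfg, method = "com")
  expect_equal(unname(p), cbind(1:3, 1:3))

  cfg2 <- track_config(cost_method = "com", solver = "greedy", greedy_threshold = 0.5)
  expect_equal(nrow(solve_greedy(d, cfg2, method = "com")), 0L)

  set.seed(34)
  for (rep in 1:50) {
    a <- matrix(round(runif(25, 0, 20), 2), 5, 5)
    tau <- runif(1, 2, 15)
    cfg3 <- track_config(cost_method = "com", solver = "greedy", greedy_threshold = tau)
    expect_equal(unname(solve_greedy(a, cfg3, method = "com")),
                 unname(oracle_greedy(a, tau, maximize = FALSE)))
    cfg4 <- track_config(cost_method = "overlap", solver = "greedy", greedy_threshold = tau)
    expect_equal(unname(solve_greedy(a, cfg4, method = "overlap")),
                 unname(oracle_greedy(a, tau, maximize = TRUE)))
  }
})

test_that("greedy with infinite tolerance matches Hungarian on easy matrices", {
  set.seed(35)
  for (rep in 1:20) {
    # matrix whose row minima sit in distinct columns
    n <- 5
    a <- matrix(runif(n * n, 10, 20), n, n)
    perm <- sample(n)
    for (i in seq_len(n)) a[i, perm[i]] <- runif(1, 0, 1)
    cfg <- track_config(cost_method = "com", solver = "greedy", greedy_threshold = Inf)
    pg <- solve_greedy(a, cfg, method = "com")
    ph <- solve_hungarian(a)
    expect_equal(pg[order(pg[, "i"]), "j"], ph[order(ph[, "i"]), "j"],
                 ignore_attr = TRUE)
  }
})

test_that("a single crawler yields one trajectory over all frames", {
  models <- lapply(seq_len(100), function(t)
    fake_model(head = c(10 + t, 20), tail = c(10 + t - 20, 20)))
  tracks <- track_models(lapply(models, list),
                         track_config(cost_method = "com", solver = "greedy",
                                      greedy_threshold = 10))
  expect_length(tracks, 1L)
  expect_equal(trajectory_frames(tracks[[1]]), 1:100)
  expect_true(tracks[[1]]$active)
})

test_that("trajectory bookkeeping: no merges, unique frames, id counter", {
  # two animals; the second disappears at frame 6, a third appears at 8
  mk <- function(x, y) fake_model(head = c(x, y), tail = c(x - 15, y))
  frames <- lapply(1:12, function(t) {
    ms <- list(mk(30 + t, 20))
    if (t <= 5) ms <- c(ms, list(mk(30 + t, 80)))
    if (t >= 8) ms <- c(ms, list(mk(90, 50 + t)))
    ms
  })
  tracks <- track_models(frames, track_config(cost_method = "com",
                                              solver = "greedy",
                                              greedy_threshold = 10))
  expect_length(tracks, 3L)
  ids <- vapply(tracks, `[[`, integer(1), "id")
  expect_equal(sort(ids), 1:3)
  spans <- lapply(tracks, trajectory_frames)
  expect_true(all(vapply(spans, function(s) all(diff(s) == 1), logical(1))))
  expect_equal(sort(vapply(tracks, function(tr) length(tr$models), integer(1))),
               c(5L, 5L, 12L))
})

test_that("colliding animals lose identity and respawn after separation", {
  co <- cached("collision_tracks", {
    out <- render_scene(scenario("collision", seed = 4))
    list(scene = out,
         tracks = track_sequence(out$frames,
                                 seg = seg_config(area_min = 100, area_max = 520),
                                 postprocess = FALSE))
  })
  tracks <- co$tracks
  expect_length(tracks, 4L)
  active <- vapply(tracks, `[[`, logical(1), "active")
  ends <- vapply(tracks, function(tr) max(trajectory_frames(tr)), integer(1))
  starts <- vapply(tracks, `[[`, integer(1), "start")
  # the two original identities terminate at the same pre-merge frame ...
  expect_equal(sum(!active), 2L)
  expect_length(unique(ends[!active]), 1L)
  # ... and two new identities appear together after the split
  expect_equal(sum(starts > 1), 2L)
  expect_length(unique(starts[starts > 1]), 1L)
})

test_that("five non-interacting crawlers are tracked without any error", {
  run <- forward_run()
  expect_length(run$tracks, 5L)
  expect_equal(run$report$n_switches, 0L)
  expect_length(run$report$lost, 0L)
  expect_true(all(vapply(run$tracks, function(tr)
    length(tr$models) == 200L, logical(1))))
})
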