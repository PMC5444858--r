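# Bending angle, sweep classification, spine length, coil indicator,
# path/velocity/acceleration series and go-phase extraction.

test_that("bending angle: straight, perpendicular, and the arccos oracle", {
  expect_equal(bending_angle(c(0, 0), c(10, 0), c(20, 0)), 180)

  g <- bending_angle(c(10, 10), c(10, 0), c(20, 0))
  expect_equal(abs(g - 180), 90)

  set.seed(51)
  for (rep in 1:1000) {
    h <- runif(2, -50, 50); s <- runif(2, -50, 50); t <- runif(2, -50, 50)
    v1 <- h - s; v2 <- s - t
    if (sqrt(sum(v1^2)) < 1e-6 || sqrt(sum(v2^2)) < 1e-6) next
    g <- bending_angle(h, s, t)
    dev_oracle <- acos(max(-1, min(1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    expect_equal(abs(g - 180), dev_oracle, tolerance = 1e-9)
  }

  expect_true(is.na(bending_angle(c(1, 1), c(1, 1), c(2, 2))))
})

test_that("sweep state thresholds use closed inequalities", {
  expect_equal(sweep_state(200, 20), "left")
  expect_equal(sweep_state(180, 0), "left")          # boundary: >= wins
  expect_equal(sweep_state(159, 20), "right")
  expect_equal(sweep_state(185, 20), "straight")
  for (g in seq(100, 260, by = 7)) for (tau in c(0, 5, 20, 45)) {
    expected <- if (g >= 180 + tau) "left" else if (g <= 180 - tau) "right"
                else "straight"
    expect_equal(sweep_state(g, tau), expected)
  }
})

test_that("spine length sums the landmark polyline", {
  m <- fake_model(head = c(30, 50), tail = c(0, 50), n_spine = 5)
  expect_equal(spine_length(m), 30)

  m1 <- fake_model(head = c(10, 0), tail = c(0, 0), n_spine = 1)
  expect_equal(spine_length(m1), 10)

  set.seed(52)
  for (rep in 1:20) {
    pts <- matrix(runif(14, 0, 100), 7, 2)
    m <- fake_model(head = pts[1, ], tail = pts[7, ])
    m$spine <- pts[2:6, ]
    oracle <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(spine_length(m), oracle)
  }
})

test_that("coil indicator fires on circles, not on straight capsules", {
  img <- matrix(0, 60, 60)
  img <- paint_disk_fixture(img, 30, 30, 12)
  circle_model <- build_model(single_contour(img))
  expect_true(is_coiled(circle_model))

  capsule <- build_model(single_contour(capsule_image(len = 40, r = 5)))
  expect_false(is_coiled(capsule))
})

test_that("coil indicator follows the generator's curl episode", {
  run <- coiling_run()
  feats <- features_table(run$tracks)
  truth <- run$scene$truth
  stopifnot(nrow(feats) == nrow(truth))
  # frames at the full curl fire; straight frames never do
  hold <- which(truth$coiled)
  straight <- which(abs(truth$bending - 180) < 30)
  expect_gt(mean(feats$coiled[hold]), 0.5)
  expect_equal(sum(feats$coiled[straight]), 0L)
  # bending output is flagged undefined on detected-coil frames
  expect_true(all(is.na(feats$bending[feats$coiled])))
})

test_that("accumulated distance and distance to origin behave like paths", {
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(accumulated_distance(square), c(0, 10, 20, 30, 40))
  expect_equal(distance_to_origin(square)[5], 0)

  line <- cbind(seq(0, 20, by = 5), 0)
  expect_equal(accumulated_distance(line), distance_to_origin(line))

  set.seed(53)
  walk <- apply(matrix(rnorm(2000), ncol = 2), 2, cumsum)
  expect_true(all(distance_to_origin(walk) <= accumulated_distance(walk) + 1e-9))
  expect_true(all(diff(accumulated_distance(walk)) >= 0))
})

test_that("velocity uses a centered one-second window", {
  com <- cbind(2 * (1:30), 0)          # uniform 2 px/frame
  v <- velocity(com, fps = 10)
  expect_true(all(is.na(v[1:5])))
  expect_true(all(is.na(v[26:30])))
  expect_equal(v[6:25], rep(2, 20))

  expect_equal(velocity(cbind(rep(3, 20), rep(4, 20)), fps = 10)[10], 0)

  set.seed(54)
  com <- cbind(cumsum(runif(40)), sin(1:40))
  v <- velocity(com, fps = 7)          # odd fps: half-window rounds down
  h <- 3
  for (t in (h + 1):(40 - h))
    expect_equal(v[t], sqrt(sum((com[t - h, ] - com[t + h, ])^2)) / 7)
})

test_that("acceleration is the damped absolute velocity difference", {
  expect_equal(acceleration(rep(2, 5))[1:4], rep(0, 4))
  expect_equal(acceleration(c(0, 4))[1], 2)
  expect_true(is.na(acceleration(c(1, 2))[2]))
  set.seed(55)
  v <- runif(30)
  a <- acceleration(v, divisor = 2)
  for (t in 1:29) expect_equal(a[t], abs(v[t] - v[t + 1]) / 2)
})

test_that("go phases require sustained fast straight runs", {
  cfg <- feature_config(go_velocity_threshold = 1, bend_threshold_deg = 20,
                        go_min_frames = 5L)
  vel <- rep(2, 20); gam <- rep(180, 20)
  gp <- go_phases(vel, gam, cfg)
  expect_true(all(gp$go))
  expect_equal(gp$phases, data.frame(start = 1L, end = 20L))

  # runs of tau_go - 1 never qualify
  vel2 <- rep(c(2, 2, 2, 2, 0), 4)
  gp2 <- go_phases(vel2, rep(180, 20), cfg)
  expect_false(any(gp2$go))

  set.seed(56)
  for (rep in 1:50) {
    n <- 40
    vel <- runif(n, 0, 3)
    gam <- runif(n, 120, 240)
    vel[sample(n, 4)] <- NA
    gp <- go_phases(vel, gam, cfg)
    raw <- !is.na(vel) & vel > 1 & !is.na(gam) & abs(gam - 180) < 20
    runs <- oracle_true_runs(raw)
    keep <- runs[runs$end - runs$start + 1L >= 5L, ]
    oracle_go <- rep(FALSE, n)
    for (k in seq_len(nrow(keep))) oracle_go[keep$start[k]:keep$end[k]] <- TRUE
    expect_equal(gp$go, oracle_go)
    expect_true(all(raw[gp$go]))                       # subset of raw frames
    expect_lte(nrow(gp$phases), floor(n / 5))
  }
})

test_that("feature table carries sentinels, not zeros, at undefined frames", {
  run <- forward_run()
  feats <- features_table(run$tracks, feature_config(fps = 10))
  expect_true(all(is.na(feats$velocity[feats$frame <= 5])))
  expect_true(all(!is.na(feats$velocity[feats$frame %in% 6:195])))
  expect_true(all(is.na(feats$acceleration[feats$frame == 200])))
  # d_org <= d_acc throughout
  expect_true(all(feats$dist_origin <= feats$acc_distance + 1e-9))
  # crawling animals spend most well-defined frames in a go phase
  expect_gt(mean(feats$go_phase[!is.na(feats$velocity)]), 0.5)
})

test_that("velocity tracks the true crawling speed on generator output", {
  run <- forward_run()
  feats <- features_table(run$tracks, feature_config(fps = 10))
  # true speed: 1.5 px/frame modulated by 20% peristalsis; the one-second
  # window averages the modulation out
  v <- feats$velocity[!is.na(feats$velocity)]
  expect_lt(abs(mean(v) - 1.5), 0.2)
})
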