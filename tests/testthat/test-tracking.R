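# Kalman motion model, pairing probability, assignment, track linking

test_that("kalman_predict advances position by velocity x dt", {
  st <- kalman_state(c(0, 0, 1000, 0), diag(c(16, 16, 100, 100)))
  p <- kalman_predict(st, 1 / 55)
  expect_equal(p$state[1], 1000 / 55, tolerance = 1e-12)  # 18.18 um
  expect_equal(p$state[2], 0)
  # zero velocity: position unchanged, covariance grows
  st0 <- kalman_state(c(5, 7, 0, 0), diag(4))
  p0 <- kalman_predict(st0, 0.1)
  expect_equal(p0$state[1:2], c(5, 7))
  expect_gt(p0$covariance[1, 1], st0$covariance[1, 1])
  # semigroup property of the mean: two half-steps equal one full step
  p2 <- kalman_predict(kalman_predict(st, 1 / 110), 1 / 110)
  expect_equal(p2$state, p$state, tolerance = 1e-12)
  expect_error(kalman_predict(st, 0), "dt")
})

test_that("pairing probability is the normalized Gaussian of the innovation", {
  # zero innovation -> p = 1, cost = 1
  st <- kalman_state(c(100, 200, 0, 0), diag(c(0, 0, 0, 0)))
  p1 <- pairing_probability(st, c(100, 200), meas_sd_um = 4)
  expect_equal(as.numeric(p1), 1)
  # Mahalanobis distance 2 -> p = exp(-2) ~ 0.1353, cost ~ 7.389
  p2 <- pairing_probability(st, c(100 + 2 * 4, 200), meas_sd_um = 4)
  expect_equal(as.numeric(p2), exp(-2), tolerance = 1e-12)
  expect_equal(1 / as.numeric(p2), exp(2), tolerance = 1e-12)
  expect_equal(attr(p2, "mahalanobis"), 2, tolerance = 1e-12)
  # strictly decreasing in distance
  ds <- seq(0, 4, by = 0.5)
  ps <- vapply(ds, function(d)
    as.numeric(pairing_probability(st, c(100 + d * 4, 200), 4)), numeric(1))
  expect_true(all(diff(ps) < 0))
  # singular innovation covariance -> degenerate input
  expect_error(pairing_probability(st, c(100, 200), meas_sd_um = 0),
               "singular")
})

test_that("solve_assignment handles pairing vs birth/death trade-offs", {
  # 1 track, 1 detection, cheap pairing -> paired
  sol <- solve_assignment(assignment_problem(matrix(1.5, 1, 1),
                                             birth = 10, death = 10))
  expect_equal(nrow(sol$pairs), 1)
  expect_length(sol$dead, 0)
  # crossing costs pick the diagonal
  sol2 <- solve_assignment(assignment_problem(matrix(c(1, 10, 10, 1), 2, 2),
                                              birth = 50, death = 50))
  expect_equal(sol2$pairs[order(sol2$pairs[, 1]), 2], c(1, 2))
  # 1 track, 0 detections -> death
  sol3 <- solve_assignment(assignment_problem(matrix(0, 1, 0)))
  expect_equal(sol3$dead, 1L)
  expect_equal(nrow(sol3$pairs), 0)
  # expensive pairing loses to birth + death
  sol4 <- solve_assignment(assignment_problem(matrix(100, 1, 1),
                                              birth = 10, death = 10))
  expect_equal(nrow(sol4$pairs), 0)
  expect_equal(sol4$dead, 1L)
  expect_equal(sol4$born, 1L)
})

test_that("assignment equals brute force on random augmented instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(1:3, 1); m <- sample(1:3, 1)
    pr <- assignment_problem(matrix(runif(n * m, 0.2, 20), n, m),
                             birth = runif(1, 1, 15), death = runif(1, 1, 15))
    sol <- solve_assignment(pr)
    expect_equal(sol$total_cost, brute_force_assignment_cost(pr$cost),
                 tolerance = 1e-9)
  }
})

test_that("link_tracks recovers a constant-velocity bubble", {
  # 36.36 um/frame at 55 Hz over 10 frames -> one track at 2 mm/s
  locs <- data.frame(frame = 1:10,
                     x_um = 100 + (0:9) * 2000 / 55,
                     y_um = 400, score = 0.9)
  tr <- link_tracks(locs, 55)
  expect_length(tr, 1)
  sp <- sqrt(tr[[1]]$vx_um_s^2 + tr[[1]]$vy_um_s^2)[-1] / 1000
  expect_equal(mean(sp), 2, tolerance = 0.05)
  expect_equal(nrow(tr[[1]]), 10)
})

test_that("tracks below 3 frames are discarded", {
  locs2 <- data.frame(frame = 1:2, x_um = c(100, 136), y_um = 400, score = 1)
  expect_length(link_tracks(locs2, 55), 0)
  locs3 <- data.frame(frame = 1:3, x_um = c(100, 136, 172), y_um = 400,
                      score = 1)
  tr3 <- link_tracks(locs3, 55)
  expect_length(tr3, 1)
  expect_equal(attr(tr3, "n_discarded"), 0)
})

test_that("well-separated opposite streams do not swap identities", {
  up <- data.frame(frame = 1:8, x_um = 100 + (0:7) * 36, y_um = 200,
                   score = 1)
  down <- data.frame(frame = 1:8, x_um = 900 - (0:7) * 36, y_um = 600,
                     score = 1)
  tr <- link_tracks(rbind(up, down), 55)
  expect_length(tr, 2)
  for (t in tr) {
    expect_equal(sd(t$y_um), 0)      # never jumps between the two lanes
    expect_equal(nrow(t), 8)
  }
  vx <- vapply(tr, function(t) mean(t$vx_um_s[-1]), numeric(1))
  expect_equal(sort(sign(vx)), c(-1, 1))
})

test_that("recovered speed is frame-rate aware", {
  # the same physical transit sampled at 55 and 27.5 Hz gives the same speed
  for (fr in c(55, 27.5)) {
    step <- 2000 / fr
    locs <- data.frame(frame = 1:8, x_um = 100 + (0:7) * step, y_um = 300,
                       score = 1)
    tr <- link_tracks(locs, fr)
    expect_length(tr, 1)
    expect_equal(mean(sqrt(tr[[1]]$vx_um_s^2 + tr[[1]]$vy_um_s^2)[-1]) / 1000,
                 2, tolerance = 0.02)
  }
})

test_that("clutter-free synthetic scene: full recall, no swaps", {
  cfg <- test_config(duration_s = 4)
  seg <- straight_vessel(cfg, speed_mm_s = 2)
  scene <- simulate_bubbles(list(seg), 0.03, cfg, seed = 17, jitter_sd_um = 0.5)
  truth_tracks <- unique(scene$bubbles$track_id)
  # feed the true positions directly (tests the tracker in isolation)
  locs <- data.frame(frame = scene$bubbles$frame,
                     x_um = scene$bubbles$x_um, y_um = scene$bubbles$y_um,
                     score = 1)
  tr <- link_tracks(locs, cfg$frame_rate_hz)
  truth_long <- sum(table(scene$bubbles$track_id) >= 3)
  expect_gte(length(tr) / truth_long, 0.95)
  sp <- unlist(lapply(tr, function(t)
    sqrt(t$vx_um_s^2 + t$vy_um_s^2)[-1])) / 1000
  expect_equal(mean(sp), 2, tolerance = 0.1)
})
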