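# the five vascular readouts

test_that("tortuosity: analytic fixtures", {
  expect_equal(tortuosity(cbind(c(0, 1, 2), c(0, 0, 0)), eps_um = 0.1), 1.0)
  expect_equal(tortuosity(cbind(c(0, 1, 1), c(0, 0, 1)), eps_um = 0.1),
               2 / sqrt(2), tolerance = 1e-12)
  th <- seq(0, pi, length.out = 100)
  r <- 50
  half_circle <- cbind(r * cos(th), r * sin(th))
  expect_equal(tortuosity(half_circle, eps_um = 1), pi / 2, tolerance = 0.01)
  # near-closed trajectory excluded
  closed <- cbind(c(0, 10, 0.5), c(0, 10, 0.2))
  expect_true(is.na(tortuosity(closed, eps_um = 8)))
})

test_that("tortuosity is invariant to rigid motion and scaling", {
  set.seed(12)
  P <- cbind(cumsum(runif(20, 1, 3)), cumsum(rnorm(20)))
  t0 <- tortuosity(P, eps_um = 0.1)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  expect_equal(tortuosity(P %*% R + 100, eps_um = 0.1), t0, tolerance = 1e-12)
  expect_equal(tortuosity(3.7 * P, eps_um = 0.1), t0, tolerance = 1e-12)
})

test_that("fractal dimension: plane, line, Sierpinski carpet", {
  expect_equal(as.numeric(fractal_dimension(matrix(TRUE, 256, 256))), 2,
               tolerance = 0.05)
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_equal(as.numeric(fractal_dimension(line)), 1, tolerance = 0.05)
  sierp <- function(n) {
    if (n == 0) return(matrix(TRUE, 1, 1))
    s <- sierp(n - 1); z <- matrix(FALSE, nrow(s), ncol(s))
    rbind(cbind(s, s, s), cbind(s, z, s), cbind(s, s, s))
  }
  fd <- fractal_dimension(sierp(4), scales = c(1, 3, 9, 27))
  expect_equal(as.numeric(fd), log(8) / log(3), tolerance = 0.05)
  expect_error(fractal_dimension(matrix(FALSE, 8, 8)), "empty")
})

test_that("fractal dimension is near-monotone under union", {
  hline <- matrix(FALSE, 256, 256); hline[100, ] <- TRUE
  vline <- matrix(FALSE, 256, 256); vline[, 60] <- TRUE
  f_cross <- as.numeric(fractal_dimension(hline | vline))
  expect_gte(f_cross, max(as.numeric(fractal_dimension(hline)),
                          as.numeric(fractal_dimension(vline))) - 0.05)
  sierp <- function(n) {
    if (n == 0) return(matrix(TRUE, 1, 1))
    s <- sierp(n - 1); z <- matrix(FALSE, nrow(s), ncol(s))
    rbind(cbind(s, s, s), cbind(s, z, s), cbind(s, s, s))
  }
  S <- sierp(4)
  L <- matrix(FALSE, 81, 81); L[40, ] <- TRUE
  sc3 <- c(1, 3, 9, 27)
  f_u <- as.numeric(fractal_dimension(S | L, scales = sc3))
  expect_gte(f_u, max(as.numeric(fractal_dimension(S, scales = sc3)),
                      as.numeric(fractal_dimension(L, scales = sc3))) - 0.05)
})

test_that("mean_velocity averages map pixels on the support", {
  cfg <- test_config(duration_s = 0.1)
  mk <- function(x, y, vx) data.frame(frame = seq_along(x), x_um = x,
                                      y_um = y, vx_um_s = vx, vy_um_s = 0,
                                      score = 1)
  t1 <- mk(seq(300, 700, by = 36), rep(300, 12), 2000)
  maps1 <- ulm_maps(list(t1), cfg)
  expect_equal(mean_velocity(maps1), 2, tolerance = 0.1)
  # two equal-support vessels at 1 and 3 mm/s -> mean 2
  t2 <- mk(seq(300, 700, by = 36), rep(500, 12), 1000)
  t3 <- mk(seq(300, 700, by = 36), rep(600, 12), 3000)
  maps2 <- ulm_maps(list(t2, t3), cfg)
  expect_equal(mean_velocity(maps2), 2, tolerance = 0.15)
  # zero-velocity samples with nonzero density average to zero
  t0 <- mk(rep(500, 5), rep(300, 5), 0)
  maps0 <- ulm_maps(list(t0), cfg, binarize = list(threshold = 0.01,
                                                   min_area_px = 1))
  expect_equal(mean_velocity(maps0), 0)
  expect_equal(mean_velocity(maps2, list(t2, t3), method = "tracks"), 2,
               tolerance = 0.01)
})

test_that("vessel_density is the covered ROI fraction", {
  roi <- matrix(TRUE, 10, 10)
  expect_equal(vessel_density(roi, roi), 1)
  expect_equal(vessel_density(matrix(FALSE, 10, 10), roi), 0)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(vessel_density(half, roi), 0.5)
  expect_error(vessel_density(half, matrix(FALSE, 10, 10)), "empty ROI")
  # monotone under dilation
  m <- matrix(FALSE, 30, 30); m[14:16, 5:25] <- TRUE
  d1 <- vessel_density(m)
  d2 <- vessel_density(ulmr:::dilate_mask(m, 2))
  expect_gte(d2, d1)
})

test_that("mean_diameter: bands, disk, linear scaling", {
  # horizontal band 10 fine px tall at 4 um -> 40 um
  band <- matrix(FALSE, 40, 120); band[16:25, ] <- TRUE
  expect_equal(as.numeric(mean_diameter(band, 4)), 40, tolerance = 4)
  # two disjoint bands of 10 and 20 px -> mean of 40 and 80 = 60 um
  two <- matrix(FALSE, 80, 120)
  two[11:20, ] <- TRUE; two[51:70, ] <- TRUE
  expect_equal(as.numeric(mean_diameter(two, 4)), 60, tolerance = 6)
  # disk of radius 20 px: diameter at the central skeleton ~ 160 um
  disk <- outer(1:81, 1:81, function(r, c) sqrt((r - 41)^2 + (c - 41)^2) <= 20)
  expect_equal(as.numeric(mean_diameter(disk, 4)), 160, tolerance = 16)
  # factor-2 upsampled band -> 2x diameter within 5%
  band2 <- ulmr:::cpp_bicubic_resize(band * 1, 2) > 0.5
  d1 <- as.numeric(mean_diameter(band, 4))
  d2 <- as.numeric(mean_diameter(band2, 4))
  expect_equal(d2 / d1, 2, tolerance = 0.05)
  expect_error(mean_diameter(matrix(FALSE, 5, 5), 4), "empty")
})

test_that("compute_metrics bundles the five readouts consistently", {
  cfg <- test_config(duration_s = 4)
  seg <- straight_vessel(cfg, diameter_um = 40, speed_mm_s = 2)
  scene <- simulate_bubbles(list(seg), 0.08, cfg, seed = 3, jitter_sd_um = 1)
  tracks <- Filter(function(t) nrow(t) >= 3,
                   split(scene$bubbles, scene$bubbles$track_id))
  maps <- ulm_maps(tracks, cfg)
  met <- compute_metrics(tracks, maps, cfg)
  expect_gte(met$tortuosity, 1)
  expect_true(met$fractal_dimension >= 0 && met$fractal_dimension <= 2)
  expect_equal(met$mean_velocity_mm_s, 2, tolerance = 0.2)
  expect_true(met$vessel_density > 0 && met$vessel_density < 1)
  expect_equal(met$n_tracks, length(tracks))
  # ROI restriction: a ROI away from the vessel has zero coverage
  roi <- matrix(FALSE, nrow(maps$mask), ncol(maps$mask))
  roi[1:10, 1:10] <- TRUE
  expect_equal(vessel_density(maps$mask, roi), 0)
})
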