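# synthetic scene generator: vessel trees, phantoms, bubble kinematics,
# rendering, tissue motion

test_that("acquisition_config validates its invariants", {
  cfg <- acquisition_config()
  expect_equal(cfg$pixel_size_um / cfg$fine_pixel_um, 8)
  expect_error(acquisition_config(pixel_size_um = 30, fine_pixel_um = 4),
               "integer multiple")
  expect_error(acquisition_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(acquisition_config(duration_s = 0.01), "at least 3 frames")
})

test_that("generate_vessel_tree: straight, deterministic, tortuous", {
  # tortuosity_level 0 -> exactly straight: arc/chord ratio 1
  segs <- generate_vessel_tree(1, 0, c(20, 60), fov = c(2048, 2048), seed = 7)
  expect_length(segs, 1)
  expect_equal(tortuosity(segs[[1]]$centerline, eps_um = 1), 1.0,
               tolerance = 1e-12)
  # determinism
  segs2 <- generate_vessel_tree(1, 0, c(20, 60), fov = c(2048, 2048), seed = 7)
  expect_identical(segs[[1]]$centerline, segs2[[1]]$centerline)
  # high tortuosity -> every branch ratio > 1.05
  segs3 <- generate_vessel_tree(3, 0.8, c(20, 60), fov = c(2048, 2048), seed = 1)
  ratios <- vapply(segs3, function(s) tortuosity(s$centerline, eps_um = 1),
                   numeric(1))
  expect_true(all(ratios > 1.05))
  expect_error(generate_vessel_tree(0, 0.5), "n_branches")
})

test_that("two-vessel phantom geometry and preconditions", {
  cfg <- test_config()
  sc <- make_two_vessel_phantom(28.5, cfg)
  ys <- vapply(sc$segments, function(s) s$centerline[1, 2], numeric(1))
  expect_equal(abs(diff(ys)), 28.5)
  expect_lt(abs(diff(ys)), cfg$pixel_size_um)  # below one coarse pixel
  sc2 <- make_two_vessel_phantom(320, cfg)
  ys2 <- vapply(sc2$segments, function(s) s$centerline[1, 2], numeric(1))
  expect_equal(abs(diff(ys2)), 320)  # 10 coarse pixels apart
  expect_error(make_two_vessel_phantom(2, cfg), "fine pixel")
  expect_error(make_two_vessel_phantom(-1, cfg), "separation_um")
})

test_that("simulate_bubbles kinematics: displacement, zero rate, zero speed", {
  cfg <- test_config()
  seg <- straight_vessel(cfg, speed_mm_s = 2)
  scene <- simulate_bubbles(list(seg), 0.1, cfg, seed = 5, jitter_sd_um = 0)
  # per-frame displacement = speed / frame rate = 2000/55 um
  b <- scene$bubbles
  tr <- b[b$track_id == b$track_id[1], ]
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(steps, rep(2000 / 55, length(steps)), tolerance = 1e-9)
  # stored truth velocity = displacement x frame rate
  expect_equal(sqrt(tr$vx_um_s[1]^2 + tr$vy_um_s[1]^2), 2000, tolerance = 1e-9)
  # zero rate -> no bubbles
  expect_equal(nrow(simulate_bubbles(list(seg), 0, cfg, seed = 5)$bubbles), 0)
  # zero speed -> static positions
  seg0 <- straight_vessel(cfg, speed_mm_s = 0)
  sc0 <- simulate_bubbles(list(seg0), 0.05, cfg, seed = 5, jitter_sd_um = 0)
  if (nrow(sc0$bubbles)) {
    t0 <- sc0$bubbles[sc0$bubbles$track_id == sc0$bubbles$track_id[1], ]
    expect_equal(sd(t0$x_um), 0)
    expect_equal(sd(t0$y_um), 0)
  }
  expect_error(simulate_bubbles(list(seg), -1, cfg), "rate_per_frame")
})

test_that("ground-truth speeds stay within 5% of segment speed (plug flow)", {
  cfg <- test_config(duration_s = 4)
  seg <- straight_vessel(cfg, speed_mm_s = 2)
  scene <- simulate_bubbles(list(seg), 0.1, cfg, seed = 9, jitter_sd_um = 0.5)
  sp <- sqrt(scene$bubbles$vx_um_s^2 + scene$bubbles$vy_um_s^2) / 1000
  expect_true(all(abs(sp - 2) / 2 <= 0.05))
})

test_that("bubble appearance is Poisson at the configured rate", {
  cfg <- acquisition_config(duration_s = 1000 / 55,
                            field_of_view = c(24L, 32L))
  seg <- straight_vessel(cfg)
  rate <- 0.2
  scene <- simulate_bubbles(list(seg), rate, cfg, seed = 123)
  n_frames_total <- floor(cfg$duration_s * cfg$frame_rate_hz)
  births <- nrow(unique(scene$bubbles[, "track_id", drop = FALSE]))
  se <- sqrt(rate / n_frames_total)
  expect_lt(abs(births / n_frames_total - rate), 3 * se)
})

test_that("rendering: blob position, empty scene, determinism, linearity", {
  cfg <- test_config(duration_s = 0.1)
  sc <- manual_scene(bubble_df(1:3, 1L, 500.3, 382.7), cfg)
  rnd <- render_frames(sc, psf_sigma_um = 100, noise = noise_free)
  fr <- rnd$ceus$frames[1, , ]
  am <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  # argmax in the coarse pixel containing the bubble
  expect_equal(unname(am["row"]), ceiling(382.7 / 32))
  expect_equal(unname(am["col"]), ceiling(500.3 / 32))
  # zero bubbles + zero noise -> all-zero CEUS
  sc0 <- manual_scene(bubble_df(integer(), integer(), numeric(), numeric()), cfg)
  rnd0 <- render_frames(sc0, noise = noise_free)
  expect_true(all(rnd0$ceus$frames == 0))
  # bit-identical re-render
  rnd2 <- render_frames(sc, psf_sigma_um = 100, noise = noise_free)
  expect_identical(rnd$ceus$frames, rnd2$ceus$frames)
  expect_identical(rnd$bmode$frames, rnd2$bmode$frames)
  # blob integral proportional to amplitude
  mass <- function(a) {
    r <- render_frames(sc, psf_sigma_um = 100,
                       noise = list(background_level = 0, speckle_contrast = 0,
                                    bubble_amplitude_range = c(a, a)))
    sum(r$ceus$frames[1, , ])
  }
  expect_equal(mass(2) / mass(0.5), 4, tolerance = 1e-9)
  expect_error(render_frames(sc, psf_sigma_um = 0), "psf_sigma_um")
})

test_that("tissue motion fields: identity, quarter-period, nonrigid bound", {
  cfg <- acquisition_config(frame_rate_hz = 20, duration_s = 1,
                            field_of_view = c(24L, 32L))
  sc <- manual_scene(bubble_df(1L, 1L, 500, 400), cfg)
  # zero amplitudes -> identity fields
  sc0 <- apply_tissue_motion(sc, list(translation_amplitude_um = 0,
                                      period_s = 1, nonrigid_amplitude_um = 0))
  expect_true(all(vapply(sc0$motion$fields, function(f)
    max(abs(c(f$dx, f$dy))), numeric(1)) == 0))
  # 64 um translation, period 1 s, frame 6 is t = 0.25 s -> uniform 64 um
  sc1 <- apply_tissue_motion(sc, list(translation_amplitude_um = 64,
                                      period_s = 1, nonrigid_amplitude_um = 0))
  f6 <- sc1$motion$fields[[6]]
  expect_equal(max(abs(f6$dx - 64)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f6$dy)), 0, tolerance = 1e-9)
  # nonrigid amplitude bounds the deviation from the mean field
  sc2 <- apply_tissue_motion(sc, list(translation_amplitude_um = 0,
                                      period_s = 1,
                                      nonrigid_amplitude_um = 10))
  dev <- vapply(sc2$motion$fields, function(f) {
    dx <- f$dx - mean(f$dx); dy <- f$dy - mean(f$dy)
    max(sqrt(dx^2 + dy^2))
  }, numeric(1))
  expect_true(all(dev <= 10 + 1e-9))
  expect_error(apply_tissue_motion(sc, list(translation_amplitude_um = -1)),
               "amplitudes")
})

test_that("scenes are bit-identical under the same seed", {
  cfg <- test_config(duration_s = 1)
  seg <- straight_vessel(cfg)
  s1 <- simulate_bubbles(list(seg), 0.1, cfg, seed = 42)
  s2 <- simulate_bubbles(list(seg), 0.1, cfg, seed = 42)
  expect_identical(s1$bubbles, s2$bubbles)
  p1 <- make_two_vessel_phantom(28.5, cfg, seed = 3)
  p2 <- make_two_vessel_phantom(28.5, cfg, seed = 3)
  expect_identical(p1$bubbles, p2$bubbles)
})

test_that("write_scene emits CSV + JSON + TIFF", {
  cfg <- test_config(duration_s = 0.1)
  sc <- manual_scene(bubble_df(1:3, 1L, 500, 400), cfg)
  d <- withr::local_tempdir()
  files <- write_scene(sc, d)
  expect_true(all(file.exists(files)))
  b <- read.csv(file.path(d, "bubbles.csv"))
  expect_equal(names(b), c("frame", "track_id", "x_um", "y_um",
                           "vx_um_s", "vy_um_s"))
  arr <- read_tiff_stack(file.path(d, "ceus.tif"))
  expect_equal(dim(arr), c(5, 24, 32))
})
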