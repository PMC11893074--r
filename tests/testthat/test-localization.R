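# normalization, PSF estimation, upsampling, NCC localization

test_that("normalize_sequence divides by the sequence-wide maximum", {
  cfg <- test_config(duration_s = 0.1)
  arr <- array(0, c(2, 4, 4))
  arr[1, 2, 2] <- 10; arr[2, 3, 3] <- 50
  fs <- frame_sequence(arr, 32, 55)
  nz <- normalize_sequence(fs)
  expect_equal(max(nz$frames[1, , ]), 0.2)
  expect_equal(max(nz$frames[2, , ]), 1.0)
  # idempotent
  expect_identical(normalize_sequence(nz)$frames, nz$frames)
  expect_error(normalize_sequence(frame_sequence(array(0, c(1, 4, 4)), 32, 55)),
               "all-zero")
})

test_that("estimate_psf recovers the rendering sigma from moving bubbles", {
  cfg <- test_config(duration_s = 2)
  seg <- straight_vessel(cfg)
  scene <- simulate_bubbles(list(seg), 0.05, cfg, seed = 4)
  rnd <- render_frames(scene, psf_sigma_um = 100)
  psf <- estimate_psf(normalize_sequence(rnd$ceus), config = cfg)
  expect_false(psf$parametric_fallback)
  expect_equal(mean(psf$sigma_um), 100, tolerance = 0.1)
  expect_equal(max(psf$kernel), 1)
  expect_true(all(dim(psf$kernel) %% 2 == 1))
  # pure noise -> degenerate input
  set.seed(1)
  noise <- frame_sequence(array(abs(rnorm(5 * 24 * 32, 0, 1e-3)),
                                c(5, 24, 32)), 32, 55)
  expect_error(estimate_psf(normalize_sequence(noise), config = cfg),
               "no local maxima|no usable")
})

test_that("a single repeated blob reproduces itself as the PSF", {
  cfg <- test_config(duration_s = 0.15)
  sc <- manual_scene(bubble_df(1:8, 1L, 496, 368), cfg)  # pixel-center blob
  rnd <- render_frames(sc, psf_sigma_um = 100, noise = noise_free)
  psf <- estimate_psf(normalize_sequence(rnd$ceus), config = cfg)
  K <- ulmr:::gaussian_kernel_fine(100, cfg)
  r <- (min(nrow(psf$kernel), nrow(K)) - 1) / 2
  cen <- function(M, r) {
    c0 <- (nrow(M) + 1) / 2
    M[(c0 - r):(c0 + r), (c0 - r):(c0 + r)]
  }
  expect_gt(cor(as.vector(cen(psf$kernel, r)), as.vector(cen(K, r))), 0.999)
})

test_that("upsample_to_fine: shape, constants, exact linear ramps", {
  cfg <- acquisition_config(field_of_view = c(32L, 64L), duration_s = 1)
  expect_equal(dim(upsample_to_fine(matrix(0, 32, 64), cfg)), c(256, 512))
  expect_true(all(upsample_to_fine(matrix(7, 8, 8), cfg) == 7))
  m <- outer(1:8, 1:6, function(a, b) 2 * a + 3 * b)
  u <- upsample_to_fine(m, cfg)
  tr <- outer((0:63) / 8 + 1, (0:47) / 8 + 1, function(a, b) 2 * a + 3 * b)
  expect_lt(max(abs(u - tr)) / max(abs(tr)), 1e-6)
  # coarse sample points preserved exactly (corner-aligned)
  expect_equal(u[seq(1, 57, by = 8), seq(1, 41, by = 8)], unname(m))
  bad <- acquisition_config(field_of_view = c(8L, 8L), duration_s = 1)
  bad$fine_pixel_um <- 32 / 7.5  # corrupt the ratio past construction
  expect_error(upsample_to_fine(matrix(0, 8, 8), bad), "integer")
})

test_that("localize_frame: autocorrelation peak, two blobs, blank frame", {
  cfg <- test_config()
  psf <- test_psf(cfg)
  # the kernel localizes itself at its center with score 1
  loc <- localize_frame(psf$kernel, psf, 0.6, cfg, frame = 1L)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$score, 1, tolerance = 1e-6)
  cen_um <- ulmr:::fine_to_um((nrow(psf$kernel) + 1) / 2, cfg)
  expect_equal(loc$x_um, cen_um, tolerance = 1e-6)
  expect_equal(loc$y_um, cen_um, tolerance = 1e-6)
  # two blobs 400 um apart -> 2 localizations within 4 um each
  sc <- manual_scene(bubble_df(c(1, 1), 1:2, c(300, 700), c(384, 384)), cfg)
  rnd <- render_frames(sc, noise = noise_free)
  fine <- upsample_to_fine(rnd$ceus$frames[1, , ], cfg)
  loc2 <- localize_frame(fine, psf, 0.6, cfg, frame = 1L)
  expect_equal(nrow(loc2), 2)
  loc2 <- loc2[order(loc2$x_um), ]
  expect_lt(abs(loc2$x_um[1] - 300), 4)
  expect_lt(abs(loc2$x_um[2] - 700), 4)
  expect_lt(max(abs(loc2$y_um - 384)), 4)
  # blank frame -> empty result
  expect_equal(nrow(localize_frame(matrix(0, 96, 96), psf, 0.6, cfg)), 0)
  expect_error(localize_frame(fine, psf, 1.2, cfg), "threshold")
})

test_that("noise-free localization error is below one fine pixel", {
  cfg <- test_config(duration_s = 0.1)
  psf <- test_psf(cfg)
  set.seed(8)
  for (i in 1:5) {
    x <- runif(1, 300, 700); y <- runif(1, 300, 500)
    sc <- manual_scene(bubble_df(1L, 1L, x, y), cfg)
    rnd <- render_frames(sc, noise = noise_free)
    fine <- upsample_to_fine(rnd$ceus$frames[1, , ], cfg)
    loc <- localize_frame(fine, psf, 0.6, cfg)
    expect_equal(nrow(loc), 1)
    expect_lt(abs(loc$x_um - x), 4)
    expect_lt(abs(loc$y_um - y), 4)
  }
})

test_that("detections are monotone in threshold and invariant to scaling", {
  cfg <- test_config(duration_s = 0.1)
  psf <- test_psf(cfg)
  sc <- manual_scene(bubble_df(rep(1, 3), 1:3, c(250, 520, 790),
                               c(350, 420, 380)), cfg)
  rnd <- render_frames(sc, psf_sigma_um = 100, noise_seed = 5L)
  fine <- upsample_to_fine(rnd$ceus$frames[1, , ], cfg)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(localize_frame(fine, psf, th, cfg)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # affine intensity scaling leaves scores unchanged (ZNCC property)
  l1 <- localize_frame(fine, psf, 0.6, cfg)
  l2 <- localize_frame(3.7 * fine + 0.2, psf, 0.6, cfg)
  expect_equal(l1$score, l2$score, tolerance = 1e-6)
  expect_equal(l1$x_um, l2$x_um, tolerance = 1e-4)
})
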