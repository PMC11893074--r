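# two-stage motion estimation and CEUS correction

px <- 32

test_that("affine estimation recovers identity, shifts and rotations", {
  ref <- speckle_frame(64)
  # identity
  tf0 <- estimate_global_affine(ref, ref, px)
  expect_lt(max(abs(tf0$translation_um)) / px, 0.1)
  # exact 2-coarse-pixel shift: content displaced +2 px in x
  mov <- ulmr:::cpp_warp_affine(ref, 1, 0, 0, 1, -2, 0)
  tf <- estimate_global_affine(ref, mov, px)
  expect_lt(abs(tf$translation_um[1] - 64) / px, 0.2)
  expect_lt(abs(tf$translation_um[2]) / px, 0.2)
  # 3 degree rotation
  th <- 3 * pi / 180
  mov2 <- ulmr:::cpp_warp_affine(ref, cos(th), -sin(th), sin(th), cos(th), 0, 0)
  tf2 <- estimate_global_affine(ref, mov2, px)
  ang <- atan2(tf2$linear[2, 1], tf2$linear[1, 1]) * 180 / pi
  expect_equal(abs(ang), 3, tolerance = 0.3)
  # residual similarity never below pre-registration similarity
  expect_gte(attr(tf, "similarity"), cor(as.vector(ref), as.vector(mov)))
  expect_error(estimate_global_affine(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
  expect_error(estimate_global_affine(ref, ref[1:32, ]), "same shape")
})

test_that("nonrigid stage: identity, known warp, pure translation", {
  ref <- speckle_frame(64)
  H <- 64; W <- 64
  # identity -> near-zero field
  fl0 <- estimate_nonrigid_bspline(ref, ref, affine_transform(), px)
  expect_lt(max(abs(c(fl0$dx, fl0$dy))) / px, 0.25)
  # known smooth sinusoidal warp of amplitude 10 um
  xs <- matrix(rep(1:W, each = H), H, W)
  ys <- matrix(rep(1:H, W), H, W)
  ux <- 10 / px * sin(2 * pi * xs / W) * cos(pi * ys / H)
  uy <- 10 / px * cos(pi * xs / W) * sin(2 * pi * ys / H)
  mov <- ulmr:::cpp_warp_bilinear(ref, -ux, -uy)
  tf <- estimate_global_affine(ref, mov, px)
  fl <- estimate_nonrigid_bspline(ref, mov, tf, px)
  roi <- 17:48
  rmse <- sqrt(mean((fl$dx[roi, roi] - ux[roi, roi] * px)^2 +
                    (fl$dy[roi, roi] - uy[roi, roi] * px)^2))
  expect_lt(rmse, 5)
  # pure 64 um translation: composed field within 5 um RMSE of truth
  mov2 <- ulmr:::cpp_warp_bilinear(ref, matrix(-2, H, W), matrix(0, H, W))
  tf2 <- estimate_global_affine(ref, mov2, px)
  fl2 <- estimate_nonrigid_bspline(ref, mov2, tf2, px)
  rmse2 <- sqrt(mean((fl2$dx[roi, roi] - 64)^2 + fl2$dy[roi, roi]^2))
  expect_lt(rmse2, 5)
})

test_that("correct_ceus: identity field, known shift, shape checks", {
  cfg <- test_config(duration_s = 0.1)
  sc <- manual_scene(bubble_df(1:5, 1L, 500.3, 382.7), cfg)
  rnd <- render_frames(sc, noise = noise_free)
  T <- dim(rnd$ceus$frames)[1]
  d <- dim(rnd$ceus$frames)[2:3]
  zero <- lapply(seq_len(T), function(f)
    deformation_field(matrix(0, d[1], d[2]), matrix(0, d[1], d[2]), f))
  out <- correct_ceus(rnd$ceus, zero)
  expect_identical(out$frames, rnd$ceus$frames)
  # bubble rendered with a known uniform shift comes back to a fixed pixel
  sc2 <- apply_tissue_motion(sc, list(translation_amplitude_um = 64,
                                      period_s = 0.07,
                                      nonrigid_amplitude_um = 0))
  rnd2 <- render_frames(sc2, noise = noise_free)
  fields <- lapply(seq_len(T), function(f)
    deformation_field(sc2$motion$fields[[f]]$dx, sc2$motion$fields[[f]]$dy, f))
  corr <- correct_ceus(rnd2$ceus, fields)
  pos <- t(vapply(seq_len(T), function(f) {
    fr <- corr$frames[f, , ]
    which(fr == max(fr), arr.ind = TRUE)[1, ]
  }, numeric(2)))
  expect_true(all(pos[, 1] == pos[1, 1]))
  expect_true(all(pos[, 2] == pos[1, 2]))
  expect_error(correct_ceus(rnd$ceus, zero[-1]), "one deformation field")
  bad <- zero; bad[[2]] <- deformation_field(matrix(0, 2, 2), matrix(0, 2, 2), 2)
  expect_error(correct_ceus(rnd$ceus, bad), "shape")
})

test_that("estimated fields raise B-mode frame-to-frame correlation", {
  cfg <- acquisition_config(duration_s = 0.2, field_of_view = c(32L, 48L))
  sc <- manual_scene(bubble_df(1:11, 1L, 700, 500), cfg)
  sc <- apply_tissue_motion(sc, list(translation_amplitude_um = 64,
                                     period_s = 0.15,
                                     nonrigid_amplitude_um = 0))
  rnd <- render_frames(sc, noise_seed = 77L)
  fields <- estimate_motion(rnd$bmode, "affine")
  bcorr <- correct_ceus(rnd$bmode, fields)
  ref <- rnd$bmode$frames[1, , ]
  T <- dim(rnd$bmode$frames)[1]
  pre <- mean(vapply(2:T, function(f)
    cor(as.vector(ref), as.vector(rnd$bmode$frames[f, , ])), numeric(1)))
  post <- mean(vapply(2:T, function(f)
    cor(as.vector(ref), as.vector(bcorr$frames[f, , ])), numeric(1)))
  expect_gt(post, pre)
})

test_that("field inversion undoes a smooth displacement", {
  H <- 40; W <- 40
  xs <- matrix(rep(1:W, each = H), H, W)
  dx <- 20 * sin(2 * pi * xs / W)   # um, ~0.6 px
  dy <- matrix(8, H, W)
  fl <- deformation_field(dx, dy, 1)
  inv <- invert_displacement_field(fl, px)
  # composing u with its inverse should be near zero away from borders
  comp_x <- dx / px + ulmr:::cpp_warp_bilinear(inv$dx / px, dx / px, dy / px)
  roi <- 10:30
  expect_lt(max(abs(comp_x[roi, roi])) * px, 1.5)
})
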