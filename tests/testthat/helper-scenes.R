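# Shared fixtures, all generated in code.

# small acquisition: 24 x 32 coarse px (768 x 1024 um), 55 Hz
test_config <- function(duration_s = 2, fov = c(24L, 32L)) {
  acquisition_config(duration_s = duration_s, field_of_view = fov)
}

# a single straight horizontal vessel with endpoints well inside the FOV
# (>= 2.5 PSF sigma from the border, so blob truncation cannot bias ends)
straight_vessel <- function(config, diameter_um = 40, speed_mm_s = 2,
                            margin_um = 280) {
  ext <- fov_um(config)
  vessel_segment(cbind(c(margin_um, ext[2] - margin_um),
                       c(ext[1] / 2, ext[1] / 2)),
                 diameter_um, speed_mm_s)
}

# speckle texture with PSF-scale correlation (for registration tests)
speckle_frame <- function(n = 64, seed = 3, sigma_px = 1.5) {
  with_seed <- get("with_seed", envir = asNamespace("ulmr"))
  with_seed(seed, {
    k <- get("gauss_kernel_1d", envir = asNamespace("ulmr"))(sigma_px)
    sc <- get("sep_convolve", envir = asNamespace("ulmr"))
    sqrt(sc(matrix(rnorm(n * n), n, n), k)^2 +
         sc(matrix(rnorm(n * n), n, n), k)^2)
  })
}

noise_free <- list(background_level = 0, speckle_contrast = 0,
                   bubble_amplitude_range = c(1, 1))

# scene holding explicit bubble observations (bypasses the flow simulator)
manual_scene <- function(bubbles, config, seed = 1L) {
  ext <- fov_um(config)
  seg <- vessel_segment(cbind(c(0, ext[2]), c(ext[1] / 2, ext[1] / 2)),
                        20, 2)
  sc <- get("new_vasc_scene", envir = asNamespace("ulmr"))
  sc(list(seg), bubbles, config, seed)
}

bubble_df <- function(frame, track_id, x_um, y_um, vx = 0, vy = 0) {
  if (!length(frame))
    return(data.frame(frame = integer(), track_id = integer(),
                      x_um = numeric(), y_um = numeric(),
                      vx_um_s = numeric(), vy_um_s = numeric()))
  data.frame(frame = frame, track_id = track_id, x_um = x_um, y_um = y_um,
             vx_um_s = vx, vy_um_s = vy)
}

# nearest-truth localization errors (um), one per localization
localization_errors <- function(locs, truth, cap_um = 150) {
  errs <- numeric(0)
  for (f in unique(locs$frame)) {
    tb <- truth[truth$frame == f, ]
    lf <- locs[locs$frame == f, ]
    if (!nrow(tb) || !nrow(lf)) next
    for (i in seq_len(nrow(lf))) {
      d <- sqrt((tb$x_um - lf$x_um[i])^2 + (tb$y_um - lf$y_um[i])^2)
      errs <- c(errs, min(min(d), cap_um))
    }
  }
  errs
}

# default Gaussian PSF model at the rendering sigma
test_psf <- function(config, sigma_um = 100) {
  K <- get("gaussian_kernel_fine", envir = asNamespace("ulmr"))(sigma_um, config)
  psf_model(K, c(sigma_um, sigma_um), config$fine_pixel_um)
}

# all-permutation brute force over a square cost matrix
brute_force_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(C[cbind(seq_len(n), p)]), numeric(1)))
}
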