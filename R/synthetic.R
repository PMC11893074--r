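# Synthetic CEUS/B-mode scene generation with complete ground truth.
#
# The generator works in the post-beamforming video domain: microbubbles are
# point scatterers imaged as an isotropic Gaussian PSF on the coarse scanner
# grid, tissue is a fixed Rayleigh speckle texture, and tissue motion is a
# global sinusoidal translation plus a smooth low-frequency nonrigid
# component. No acoustic propagation or nonlinear bubble dynamics.

#' Vessel segment ground truth
#'
#' @param centerline `N x 2` matrix of (x, y) points in um, `N >= 2`.
#' @param diameter_um Lumen diameter (um), > 0.
#' @param peak_speed_mm_s Peak (centerline) flow speed (mm/s), >= 0.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(centerline, diameter_um, peak_speed_mm_s) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 ||
      sum(sqrt(rowSums(diff(centerline)^2))) <= 0)
    stop_invalid("centerline needs >= 2 distinct points")
  if (diameter_um <= 0) stop_invalid("diameter_um must be > 0")
  if (peak_speed_mm_s < 0) stop_invalid("peak_speed_mm_s must be >= 0")
  colnames(centerline) <- c("x", "y")
  structure(list(centerline = centerline, diameter_um = diameter_um,
                 peak_speed_mm_s = peak_speed_mm_s),
            class = "vessel_segment")
}

seg_arclength <- function(seg) {
  d <- sqrt(rowSums(diff(seg$centerline)^2))
  c(0, cumsum(d))
}

# position and unit tangent at arclength s (linear interpolation)
seg_point_at <- function(seg, s, cum = seg_arclength(seg)) {
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cum) - 1L)
  f <- (s - cum[i]) / pmax(cum[i + 1] - cum[i], 1e-12)
  P <- seg$centerline
  pos <- P[i, , drop = FALSE] * (1 - f) + P[i + 1, , drop = FALSE] * f
  tan <- P[i + 1, , drop = FALSE] - P[i, , drop = FALSE]
  tan <- tan / pmax(sqrt(rowSums(tan^2)), 1e-12)
  list(pos = pos, tangent = tan)
}

#' Generate a branching vessel tree
#'
#' Random smooth centerlines inside the field of view. The first branch runs
#' left to right; further branches sprout from a random point of an existing
#' branch. Heading noise scales with `tortuosity_level`: 0 gives perfectly
#' straight segments. Deterministic given `seed`.
#'
#' @param n_branches Number of branches (>= 1).
#' @param tortuosity_level Scalar in \[0, 1\] scaling per-step heading noise.
#' @param diameter_range_um Interval `(min, max)` of lumen diameters (um).
#' @param fov `(height_um, width_um)` extent of the scene.
#' @param seed Integer RNG seed.
#' @param step_um Polyline step length (um).
#' @param speed_range_mm_s Interval of peak speeds assigned per branch (mm/s);
#'   the default brackets capillary-to-arteriolar flow at 1-5 mm/s.
#' @return List of [vessel_segment()].
#' @export
generate_vessel_tree <- function(n_branches, tortuosity_level,
                                 diameter_range_um = c(20, 60),
                                 fov = c(2048, 2048), seed = 1L,
                                 step_um = 20,
                                 speed_range_mm_s = c(1, 5)) {
  if (n_branches < 1) stop_invalid("n_branches must be >= 1")
  if (any(fov <= 0)) stop_invalid("fov must be positive")
  if (diameter_range_um[1] <= 0 || diameter_range_um[2] >= min(fov) / 4)
    stop_invalid("diameter_range must lie within (0, fov/4)")
  H <- fov[1]; W <- fov[2]
  with_seed(seed, {
    segs <- list()
    for (b in seq_len(n_branches)) {
      if (b == 1) {
        start <- c(0.05 * W, runif(1, 0.25 * H, 0.75 * H))
        theta0 <- runif(1, -0.25, 0.25)
      } else {
        parent <- segs[[sample.int(length(segs), 1)]]
        cl <- parent$centerline
        i <- sample(seq(max(2, floor(0.2 * nrow(cl))), nrow(cl) - 1), 1)
        start <- cl[i, ]
        tang <- cl[i + 1, ] - cl[i, ]
        theta0 <- atan2(tang[2], tang[1]) +
          sample(c(-1, 1), 1) * runif(1, 0.3, 0.9)
      }
      theta <- theta0
      dtheta <- 0
      pts <- matrix(start, 1, 2)
      p <- start
      for (k in seq_len(600)) {
        dtheta <- 0.5 * dtheta + tortuosity_level * 0.3 * rnorm(1)
        theta <- theta + dtheta - 0.04 * (theta - theta0)
        p <- p + step_um * c(cos(theta), sin(theta))
        if (p[1] < 0 || p[1] > W || p[2] < 0 || p[2] > H) break
        pts <- rbind(pts, p)
      }
      if (nrow(pts) < 2) next
      segs[[length(segs) + 1]] <- vessel_segment(
        pts, runif(1, diameter_range_um[1], diameter_range_um[2]),
        runif(1, speed_range_mm_s[1], speed_range_mm_s[2]))
    }
    segs
  })
}

new_vasc_scene <- function(segments, bubbles, config, seed, motion = NULL) {
  structure(list(segments = segments, bubbles = bubbles,
                 motion = motion, config = config, seed = as.integer(seed)),
            class = "vasc_scene")
}

#' @export
print.vasc_scene <- function(x, ...) {
  cat(sprintf("<vasc_scene> %d segment(s), %d bubble observations, %d frame(s)%s\n",
              length(x$segments), nrow(x$bubbles),
              n_frames_of(x$config),
              if (is.null(x$motion)) "" else ", with tissue motion"))
  invisible(x)
}

empty_bubbles <- function() {
  data.frame(frame = integer(), track_id = integer(), x_um = numeric(),
             y_um = numeric(), vx_um_s = numeric(), vy_um_s = numeric())
}

#' Simulate microbubble transits through a vessel tree
#'
#' Bubbles appear at each segment inlet as a per-frame Poisson process,
#' advect along the centerline at the segment speed with a fixed lateral
#' offset inside the lumen (plus optional small per-frame jitter), and exit
#' at the segment end. Ground-truth velocity per frame is the forward
#' displacement times the frame rate.
#'
#' @param segments List of [vessel_segment()].
#' @param rate_per_frame Expected new bubbles per frame per segment (>= 0).
#' @param config An [acquisition_config()].
#' @param seed Integer RNG seed; same seed gives a bit-identical scene.
#' @param flow_profile `"plug"` (default; all streamlines at the segment's
#'   peak speed, so ground-truth speeds are constant) or `"poiseuille"`
#'   (parabolic profile, speed = peak * (1 - rho^2) at relative radius rho).
#' @param jitter_sd_um Per-frame lateral jitter standard deviation (um).
#' @return A `vasc_scene` with the ground-truth bubble table
#'   `(frame, track_id, x_um, y_um, vx_um_s, vy_um_s)`.
#' @export
simulate_bubbles <- function(segments, rate_per_frame, config, seed = 1L,
                             flow_profile = c("plug", "poiseuille"),
                             jitter_sd_um = 0.5) {
  flow_profile <- match.arg(flow_profile)
  if (rate_per_frame < 0) stop_invalid("rate_per_frame must be >= 0")
  T <- n_frames_of(config)
  dt <- 1 / config$frame_rate_hz
  out <- list()
  next_id <- 1L
  with_seed(seed, {
    for (seg in segments) {
      cum <- seg_arclength(seg)
      L <- cum[length(cum)]
      peak_um_s <- seg$peak_speed_mm_s * 1000
      for (f in seq_len(T)) {
        n_new <- rpois(1, rate_per_frame)
        if (n_new == 0) next
        for (b in seq_len(n_new)) {
          rho <- runif(1, -1, 1)
          speed <- if (flow_profile == "plug") peak_um_s
                   else peak_um_s * (1 - rho^2)
          n_steps <- if (speed > 0) floor((L - 1e-9) / (speed * dt)) + 1L
                     else T - f + 1L
          n_steps <- min(n_steps, T - f + 1L)
          if (n_steps < 1) next
          s <- (seq_len(n_steps) - 1) * speed * dt
          pt <- seg_point_at(seg, s, cum)
          nrm <- cbind(-pt$tangent[, 2], pt$tangent[, 1])
          off <- rho * seg$diameter_um / 2
          jit <- if (jitter_sd_um > 0) rnorm(n_steps, 0, jitter_sd_um) else 0
          pos <- pt$pos + nrm * (off + jit)
          v <- rbind(diff(pos), if (n_steps > 1) diff(pos)[n_steps - 1, , drop = FALSE]
                                 else cbind(0, 0)) / dt
          out[[length(out) + 1]] <- data.frame(
            frame = f + seq_len(n_steps) - 1L, track_id = next_id,
            x_um = pos[, 1], y_um = pos[, 2],
            vx_um_s = v[, 1], vy_um_s = v[, 2])
          next_id <- next_id + 1L
        }
      }
    }
  })
  bubbles <- if (length(out)) do.call(rbind, out) else empty_bubbles()
  bubbles <- bubbles[order(bubbles$frame, bubbles$track_id), ]
  rownames(bubbles) <- NULL
  new_vasc_scene(segments, bubbles, config, seed)
}

#' Two parallel vessel resolution phantom
#'
#' Two straight horizontal vessels whose centerlines are exactly
#' `separation_um` apart (center to center), each carrying deterministic
#' single-bubble transits at a fixed speed, temporally staggered so that
#' bubbles from the two vessels are never laterally close in the same frame.
#' Used to probe the resolving power of the reconstruction below the coarse
#' pixel pitch.
#'
#' @param separation_um Center-to-center separation (um), > 0 and at least
#'   one fine pixel.
#' @param config An [acquisition_config()].
#' @param speed_mm_s Transit speed (mm/s).
#' @param diameter_um Lumen diameter (um); small relative to the separation.
#' @param seed Integer RNG seed for intraluminal offsets.
#' @return A `vasc_scene`.
#' @export
make_two_vessel_phantom <- function(separation_um, config,
                                    speed_mm_s = 2, diameter_um = 8,
                                    seed = 1L) {
  if (separation_um <= 0) stop_invalid("separation_um must be > 0")
  if (separation_um < config$fine_pixel_um)
    stop_invalid("separation_um below one fine pixel (",
                 config$fine_pixel_um, " um) cannot be represented")
  ext <- fov_um(config)
  H <- ext[1]; W <- ext[2]
  margin <- 2 * config$pixel_size_um
  yc <- H / 2
  mk <- function(y) vessel_segment(
    cbind(c(margin, W - margin), c(y, y)), diameter_um, speed_mm_s)
  segs <- list(mk(yc - separation_um / 2), mk(yc + separation_um / 2))
  T <- n_frames_of(config)
  dt <- 1 / config$frame_rate_hz
  L <- W - 2 * margin
  step <- speed_mm_s * 1000 * dt
  n_tr <- max(2L, floor(L / step) + 1L)
  spacing <- n_tr + 2L  # one bubble in flight per vessel at a time
  out <- list()
  next_id <- 1L
  with_seed(seed, {
    for (iseg in 1:2) {
      seg <- segs[[iseg]]
      cum <- seg_arclength(seg)
      starts <- seq(1L + (iseg - 1L) * (spacing %/% 2L), T, by = spacing)
      for (f0 in starts) {
        n_steps <- min(n_tr, T - f0 + 1L)
        if (n_steps < 1) next
        rho <- runif(1, -1, 1)
        s <- (seq_len(n_steps) - 1) * step
        pt <- seg_point_at(seg, s, cum)
        pos <- pt$pos
        pos[, 2] <- pos[, 2] + rho * diameter_um / 2
        v <- rbind(diff(pos), if (n_steps > 1) diff(pos)[n_steps - 1, , drop = FALSE]
                               else cbind(0, 0)) / dt
        out[[length(out) + 1]] <- data.frame(
          frame = f0 + seq_len(n_steps) - 1L, track_id = next_id,
          x_um = pos[, 1], y_um = pos[, 2],
          vx_um_s = v[, 1], vy_um_s = v[, 2])
        next_id <- next_id + 1L
      }
    }
  })
  bubbles <- if (length(out)) do.call(rbind, out) else empty_bubbles()
  bubbles <- bubbles[order(bubbles$frame, bubbles$track_id), ]
  rownames(bubbles) <- NULL
  new_vasc_scene(segs, bubbles, config, seed)
}

#' Add tissue motion to a scene
#'
#' Stores per-frame displacement fields: a spatially uniform sinusoidal
#' translation plus a smooth, zero-mean nonrigid component. Rendering shifts
#' bubbles (and warps the B-mode speckle) by these fields; the true fields
#' are retained so that estimated motion can be scored against them.
#'
#' @param scene A `vasc_scene`.
#' @param motion List with `translation_amplitude_um`, `period_s`,
#'   `nonrigid_amplitude_um` (all >= 0), optional `direction` (unit 2-vector
#'   for the translation, default along x) and `nonrigid_period_s`.
#' @return The scene with `motion$fields`: per frame, `list(dx, dy)` in um on
#'   the coarse grid.
#' @export
apply_tissue_motion <- function(scene,
                                motion = list(translation_amplitude_um = 0,
                                              period_s = 1,
                                              nonrigid_amplitude_um = 0)) {
  a_tr <- motion$translation_amplitude_um %||% 0
  a_nr <- motion$nonrigid_amplitude_um %||% 0
  period <- motion$period_s %||% 1
  period_nr <- motion$nonrigid_period_s %||% (period * 1.7)
  dir <- motion$direction %||% c(1, 0)
  if (a_tr < 0 || a_nr < 0) stop_invalid("motion amplitudes must be >= 0")
  dir <- dir / sqrt(sum(dir^2))
  cfg <- scene$config
  fovpx <- cfg$field_of_view
  H <- fovpx[1]; W <- fovpx[2]
  T <- n_frames_of(cfg)
  # fixed smooth spatial pattern, zero mean, unit peak vector magnitude
  xs <- coarse_to_um(seq_len(W), cfg)
  ys <- coarse_to_um(seq_len(H), cfg)
  ext <- fov_um(cfg)
  gx <- outer(ys, xs, function(y, x) sin(2 * pi * x / ext[2]) * cos(pi * y / ext[1]))
  gy <- outer(ys, xs, function(y, x) cos(pi * x / ext[2]) * sin(2 * pi * y / ext[1]))
  gx <- gx - mean(gx); gy <- gy - mean(gy)
  m <- max(sqrt(gx^2 + gy^2))
  if (m > 0) { gx <- gx / m; gy <- gy / m }
  fields <- vector("list", T)
  for (f in seq_len(T)) {
    t <- (f - 1) / cfg$frame_rate_hz
    tr <- a_tr * sin(2 * pi * t / period) * dir
    snr <- a_nr * sin(2 * pi * t / period_nr)
    fields[[f]] <- list(dx = tr[1] + snr * gx, dy = tr[2] + snr * gy)
  }
  scene$motion <- list(fields = fields, params = motion)
  scene
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bilinear sample of a per-frame motion field (um) at scene positions (um)
sample_field_um <- function(field, x_um, y_um, config) {
  # coarse pixel coordinates, 0-based
  cx <- um_to_coarse(x_um, config) - 1
  cy <- um_to_coarse(y_um, config) - 1
  dx <- numeric(length(x_um)); dy <- numeric(length(x_um))
  H <- nrow(field$dx); W <- ncol(field$dx)
  cx <- pmin(pmax(cx, 0), W - 1); cy <- pmin(pmax(cy, 0), H - 1)
  ix <- pmin(floor(cx), W - 2); iy <- pmin(floor(cy), H - 2)
  ix <- pmax(ix, 0); iy <- pmax(iy, 0)
  fx <- cx - ix; fy <- cy - iy
  idx <- function(M, r, c) M[cbind(r + 1, c + 1)]
  for (comp in c("dx", "dy")) {
    M <- field[[comp]]
    v <- (1 - fy) * ((1 - fx) * idx(M, iy, ix) + fx * idx(M, iy, ix + 1)) +
         fy * ((1 - fx) * idx(M, iy + 1, ix) + fx * idx(M, iy + 1, ix + 1))
    if (comp == "dx") dx <- v else dy <- v
  }
  list(dx = dx, dy = dy)
}

# true bubble positions as rendered (base position + tissue motion)
displaced_bubble_positions <- function(scene) {
  b <- scene$bubbles
  if (is.null(scene$motion) || nrow(b) == 0) return(b)
  for (f in unique(b$frame)) {
    i <- which(b$frame == f)
    d <- sample_field_um(scene$motion$fields[[f]], b$x_um[i], b$y_um[i],
                         scene$config)
    b$x_um[i] <- b$x_um[i] + d$dx
    b$y_um[i] <- b$y_um[i] + d$dy
  }
  b
}

#' Render a scene into B-mode and CEUS frame sequences
#'
#' The CEUS channel is a sum of isotropic Gaussian blobs (sigma =
#' `psf_sigma_um`, the system PSF) at the motion-displaced bubble positions,
#' sampled on the coarse grid, over a weak Rayleigh-speckle background. The
#' B-mode channel is a fixed Rayleigh speckle texture warped by the scene's
#' motion fields. Rendering is bit-reproducible given `noise_seed`.
#'
#' @param scene A `vasc_scene`.
#' @param psf_sigma_um PSF standard deviation (um); the default 100 um is of
#'   the order of the acoustic wavelength at 15 MHz.
#' @param noise List: `background_level` (CEUS background mean, relative to
#'   bubble amplitude ~1), `speckle_contrast` (relative amplitude of the
#'   Rayleigh texture), `bubble_amplitude_range` (per-bubble uniform range).
#' @param noise_seed Integer RNG seed for noise and amplitudes.
#' @return `list(bmode = , ceus = )` of [frame_sequence()] objects.
#' @export
render_frames <- function(scene, psf_sigma_um = 100,
                          noise = list(background_level = 0.05,
                                       speckle_contrast = 0.5,
                                       bubble_amplitude_range = c(0.8, 1.2)),
                          noise_seed = scene$seed + 1000L) {
  if (psf_sigma_um <= 0) stop_invalid("psf_sigma_um must be > 0")
  cfg <- scene$config
  H <- cfg$field_of_view[1]; W <- cfg$field_of_view[2]
  T <- n_frames_of(cfg)
  px <- cfg$pixel_size_um
  bg <- noise$background_level %||% 0
  spk <- noise$speckle_contrast %||% 0
  amp_range <- noise$bubble_amplitude_range %||% c(1, 1)
  bub <- displaced_bubble_positions(scene)
  xs <- coarse_to_um(seq_len(W), cfg)
  ys <- coarse_to_um(seq_len(H), cfg)
  ceus <- array(0, c(T, H, W))
  bmode <- array(0, c(T, H, W))
  with_seed(noise_seed, {
    # per-track amplitudes
    ids <- sort(unique(bub$track_id))
    amps <- if (length(ids)) runif(length(ids), amp_range[1], amp_range[2])
            else numeric()
    names(amps) <- as.character(ids)
    # fixed B-mode speckle: modulus of a PSF-correlated complex Gaussian field
    sig_px <- max(psf_sigma_um / px, 0.6)
    k1 <- gauss_kernel_1d(sig_px / 2)
    re <- sep_convolve(matrix(rnorm(H * W), H, W), k1)
    im <- sep_convolve(matrix(rnorm(H * W), H, W), k1)
    S <- sqrt(re^2 + im^2)
    S <- S / mean(S)
    rad_px <- ceiling(4 * psf_sigma_um / px)
    for (f in seq_len(T)) {
      fr <- matrix(0, H, W)
      if (bg > 0) {
        ray <- sqrt(rnorm(H * W)^2 + rnorm(H * W)^2) / sqrt(pi / 2)
        fr <- fr + bg * pmax(1 + spk * (matrix(ray, H, W) - 1), 0)
      }
      i <- which(bub$frame == f)
      for (j in i) {
        pxum <- bub$x_um[j]; pyum <- bub$y_um[j]
        A <- amps[[as.character(bub$track_id[j])]]
        c0 <- max(1L, floor(um_to_coarse(pxum, cfg)) - rad_px)
        c1 <- min(W, ceiling(um_to_coarse(pxum, cfg)) + rad_px)
        r0 <- max(1L, floor(um_to_coarse(pyum, cfg)) - rad_px)
        r1 <- min(H, ceiling(um_to_coarse(pyum, cfg)) + rad_px)
        if (c0 > c1 || r0 > r1) next
        gx <- exp(-(xs[c0:c1] - pxum)^2 / (2 * psf_sigma_um^2))
        gy <- exp(-(ys[r0:r1] - pyum)^2 / (2 * psf_sigma_um^2))
        fr[r0:r1, c0:c1] <- fr[r0:r1, c0:c1] + A * outer(gy, gx)
      }
      ceus[f, , ] <- fr
      # B-mode: tissue displaced by u -> image samples texture at x - u
      if (!is.null(scene$motion)) {
        fld <- scene$motion$fields[[f]]
        bm <- cpp_warp_bilinear(S, -fld$dx / px, -fld$dy / px)
      } else bm <- S
      bmode[f, , ] <- bm + 0.02 * matrix(rnorm(H * W), H, W)
    }
  })
  list(bmode = frame_sequence(bmode, px, cfg$frame_rate_hz, "bmode"),
       ceus = frame_sequence(ceus, px, cfg$frame_rate_hz, "ceus"))
}

#' Write a scene's ground truth and rendered frames to disk
#'
#' Ground truth goes to `bubbles.csv` (frame, track_id, x_um, y_um, vx_um_s,
#' vy_um_s) and `scene.json`; rendered channels to `bmode.tif` / `ceus.tif`
#' (multi-page float TIFF).
#'
#' @param scene A `vasc_scene`.
#' @param dir Output directory (created if missing).
#' @param render Optional pre-rendered `list(bmode, ceus)`; rendered with
#'   defaults when `NULL`.
#' @return Invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir, render = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "bubbles.csv")
  write.csv(scene$bubbles, f, row.names = FALSE)
  files <- c(files, f)
  desc <- list(
    seed = scene$seed,
    config = unclass(scene$config),
    n_segments = length(scene$segments),
    segments = lapply(scene$segments, function(s)
      list(diameter_um = s$diameter_um, peak_speed_mm_s = s$peak_speed_mm_s,
           centerline = unname(s$centerline))),
    motion = if (is.null(scene$motion)) NULL else scene$motion$params)
  f <- file.path(dir, "scene.json")
  jsonlite::write_json(desc, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  if (is.null(render)) render <- render_frames(scene)
  for (ch in c("bmode", "ceus")) {
    f <- file.path(dir, paste0(ch, ".tif"))
    write_tiff_stack(render[[ch]]$frames, f)
    files <- c(files, f)
  }
  invisible(files)
}
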