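# Tissue-motion estimation and correction.
#
# Motion is estimated on the B-mode channel against a reference frame in two
# stages: a global affine transform, then a B-spline-smoothed nonrigid
# residual fitted to local block-matching displacements. The estimated
# fields map reference coordinates to moving-frame coordinates, so warping
# the CEUS frame by the field undoes the motion ("reversed" fields): bubbles
# accumulate in reference-frame positions.

#' Affine transform (2D)
#'
#' @param linear 2x2 dimensionless linear part (x = column axis first).
#' @param translation_um Length-2 translation (um).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(2), translation_um = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) <= 1e-6)
    stop_invalid("linear part must be invertible (|det| > 1e-6)")
  structure(list(linear = linear, translation_um = as.numeric(translation_um)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  ang <- atan2(x$linear[2, 1], x$linear[1, 1]) * 180 / pi
  cat(sprintf("<affine_transform> t = (%.2f, %.2f) um, rotation ~ %.2f deg\n",
              x$translation_um[1], x$translation_um[2], ang))
  invisible(x)
}

warp_by_affine <- function(img, tf, pixel_size_um) {
  t_px <- tf$translation_um / pixel_size_um
  cpp_warp_affine(img, tf$linear[1, 1], tf$linear[1, 2],
                  tf$linear[2, 1], tf$linear[2, 2], t_px[1], t_px[2])
}

# NCC over a border-inset region (warped edges are clamped, exclude them)
ncc_inset <- function(a, b, margin) {
  H <- nrow(a); W <- ncol(a)
  m <- min(margin, (H - 2) %/% 2, (W - 2) %/% 2)
  r <- (1 + m):(H - m); c <- (1 + m):(W - m)
  ncc_global(a[r, c], b[r, c])
}

# integer-pixel translation maximizing the cross-correlation of the
# zero-mean images (FFT-based, coarse initializer for the affine search)
coarse_shift <- function(reference, moving, max_shift) {
  H <- nrow(reference); W <- ncol(reference)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  Hp <- stats::nextn(2 * H, c(2, 3, 5)); Wp <- stats::nextn(2 * W, c(2, 3, 5))
  A <- matrix(0, Hp, Wp); A[1:H, 1:W] <- a
  B <- matrix(0, Hp, Wp); B[1:H, 1:W] <- b
  R <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  sh <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  ok_r <- abs(sh(seq_len(Hp), Hp)) <= max_shift
  ok_c <- abs(sh(seq_len(Wp), Wp)) <= max_shift
  sub <- R[ok_r, ok_c, drop = FALSE]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c(dx = sh(seq_len(Wp), Wp)[ok_c][ij[2]],
    dy = sh(seq_len(Hp), Hp)[ok_r][ij[1]])
}

#' Estimate the global affine motion between two frames
#'
#' Maximizes normalized cross-correlation between the reference and the
#' affinely warped moving frame: an FFT translation initializer followed by
#' Nelder-Mead refinement of (translation, rotation, scale), then of the
#' full 6-parameter affine.
#'
#' @param reference,moving Same-shape nonconstant matrices (coarse grid).
#' @param pixel_size_um Pixel pitch (um) used to report the translation.
#' @param max_shift_px Search radius of the translation initializer.
#' @return An [affine_transform()] with attribute `"similarity"` (the final
#'   NCC).
#' @export
estimate_global_affine <- function(reference, moving, pixel_size_um = 32,
                                   max_shift_px = 16) {
  if (!all(dim(reference) == dim(moving)))
    stop_invalid("frames must have the same shape")
  if (sd(reference) == 0 || sd(moving) == 0)
    stop_degenerate("constant image: affine estimation is undefined")
  margin <- 4
  obj_warp <- function(tf) {
    w <- cpp_warp_affine(moving, tf[1], tf[2], tf[3], tf[4], tf[5], tf[6])
    -ncc_inset(reference, w, margin)
  }
  init <- coarse_shift(reference, moving, max_shift_px)
  # moving displaced by +d relative to reference => sample moving at x + d
  p0 <- c(init[["dx"]], init[["dy"]], 0, 0)
  obj_rts <- function(p) {
    s <- exp(p[4]); ct <- cos(p[3]); st <- sin(p[3])
    obj_warp(c(s * ct, -s * st, s * st, s * ct, p[1], p[2]))
  }
  o1 <- optim(p0, obj_rts, method = "Nelder-Mead",
              control = list(maxit = 400, reltol = 1e-8))
  s <- exp(o1$par[4]); ct <- cos(o1$par[3]); st <- sin(o1$par[3])
  p6 <- c(s * ct, -s * st, s * st, s * ct, o1$par[1], o1$par[2])
  o2 <- optim(p6, obj_warp, method = "Nelder-Mead",
              control = list(maxit = 600, reltol = 1e-9,
                             parscale = c(0.05, 0.05, 0.05, 0.05, 1, 1)))
  best <- if (o2$value < o1$value) o2$par else p6
  sim <- -min(o1$value, o2$value)
  # never worse than the identity
  if (sim < ncc_inset(reference, moving, margin)) {
    best <- c(1, 0, 0, 1, 0, 0)
    sim <- ncc_inset(reference, moving, margin)
  }
  tf <- affine_transform(matrix(best[1:4], 2, 2, byrow = TRUE),
                         c(best[5], best[6]) * pixel_size_um)
  attr(tf, "similarity") <- sim
  tf
}

#' Deformation field
#'
#' Per-pixel 2D displacement (um) on the coarse frame grid, mapping
#' reference coordinates to moving-frame coordinates.
#'
#' @param dx,dy Displacement components (um), matrices of the frame shape.
#' @param frame Frame index the field belongs to.
#' @param fallback TRUE when the nonrigid stage fell back to affine-only.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, frame = NA_integer_, fallback = FALSE) {
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stop_invalid("deformation field must be finite")
  if (!all(dim(dx) == dim(dy))) stop_invalid("dx and dy shapes differ")
  structure(list(dx = dx, dy = dy, frame = frame, fallback = fallback),
            class = "deformation_field")
}

affine_to_field <- function(tf, dimHW, pixel_size_um, frame = NA_integer_) {
  H <- dimHW[1]; W <- dimHW[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  xc <- matrix(rep(0:(W - 1) - cx, each = H), H, W)
  yc <- matrix(rep(0:(H - 1) - cy, W), H, W)
  t_px <- tf$translation_um / pixel_size_um
  A <- tf$linear
  dx <- (A[1, 1] * xc + A[1, 2] * yc + t_px[1]) - xc
  dy <- (A[2, 1] * xc + A[2, 2] * yc + t_px[2]) - yc
  deformation_field(dx * pixel_size_um, dy * pixel_size_um, frame)
}

#' Estimate the nonrigid residual deformation (B-spline stage)
#'
#' After applying the affine initializer, local displacements are measured
#' on a grid of blocks (integer NCC search plus continuous Nelder-Mead
#' refinement), low-confidence blocks are rejected, and the block grid is
#' smoothed/interpolated to a full-resolution field by a tensor-product
#' B-spline surface (one per component). The composed mapping is
#' `x -> A (x + r(x)) + t`. If the composed similarity falls below the
#' affine-only similarity the affine-only field is returned with a warning
#' and `fallback = TRUE`.
#'
#' @param reference,moving Same-shape matrices (coarse grid).
#' @param init An [affine_transform()] (e.g. from
#'   [estimate_global_affine()]).
#' @param pixel_size_um Pixel pitch (um).
#' @param control_spacing_px Control-point / block spacing (coarse px).
#' @param search_px Integer search radius of the block matching.
#' @param frame Frame index stored in the result.
#' @return A [deformation_field()] with attribute `"similarity"`.
#' @export
estimate_nonrigid_bspline <- function(reference, moving, init,
                                      pixel_size_um = 32,
                                      control_spacing_px = 16,
                                      search_px = 4,
                                      frame = NA_integer_) {
  if (!all(dim(reference) == dim(moving)))
    stop_invalid("frames must have the same shape")
  H <- nrow(reference); W <- ncol(reference)
  mov1 <- warp_by_affine(moving, init, pixel_size_um)
  margin <- 4
  sim_affine <- ncc_inset(reference, mov1, margin)
  # adapt the control spacing so small frames still carry a block grid
  sp <- max(4L, min(control_spacing_px, floor(min(H, W) / 6)))
  br <- max(6L, as.integer(sp * 0.75))          # block half-size
  cys <- seq(br + search_px + 1, H - br - search_px, by = sp)
  cxs <- seq(br + search_px + 1, W - br - search_px, by = sp)
  make_affine_field <- function() {
    fl <- affine_to_field(init, c(H, W), pixel_size_um, frame)
    fl$fallback <- TRUE
    attr(fl, "similarity") <- sim_affine
    fl
  }
  if (length(cys) < 2 || length(cxs) < 2) {
    warning("image too small for the nonrigid stage; affine-only fallback")
    return(make_affine_field())
  }
  pts <- expand.grid(cy = cys, cx = cxs)
  ux <- uy <- ok <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cy <- pts$cy[i]; cx <- pts$cx[i]
    ref_b <- reference[(cy - br):(cy + br), (cx - br):(cx + br)]
    if (sd(ref_b) < 1e-8) { ok[i] <- 0; next }
    best <- c(0, 0); best_v <- -2
    for (dy in -search_px:search_px)
      for (dx in -search_px:search_px) {
        mb <- mov1[(cy - br + dy):(cy + br + dy), (cx - br + dx):(cx + br + dx)]
        v <- ncc_global(ref_b, mb)
        if (v > best_v) { best_v <- v; best <- c(dx, dy) }
      }
    # continuous refinement of the block shift on a padded neighbourhood
    pad <- mov1[(cy - br - search_px):(cy + br + search_px),
                (cx - br - search_px):(cx + br + search_px)]
    obj2 <- function(p) {
      if (max(abs(p)) > search_px) return(2)
      d0 <- matrix(0, 2 * br + 1, 2 * br + 1)
      w <- cpp_warp_bilinear(pad, matrix(p[1], nrow(pad), ncol(pad)),
                             matrix(p[2], nrow(pad), ncol(pad)))
      -ncc_global(ref_b, w[(search_px + 1):(search_px + 1 + 2 * br),
                           (search_px + 1):(search_px + 1 + 2 * br)])
    }
    o <- optim(best, obj2, method = "Nelder-Mead",
               control = list(maxit = 80, reltol = 1e-7))
    if (-o$value >= best_v) { best <- o$par; best_v <- -o$value }
    ux[i] <- best[1]; uy[i] <- best[2]
    ok[i] <- as.numeric(best_v > 0.3)
  }
  keep <- ok > 0
  if (sum(keep) < 8) {
    warning("too few reliable blocks; affine-only fallback")
    return(make_affine_field())
  }
  dat <- data.frame(x = pts$cx[keep], y = pts$cy[keep],
                    ux = ux[keep], uy = uy[keep])
  kx <- min(6L, length(unique(dat$x))); ky <- min(6L, length(unique(dat$y)))
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  fit_comp <- function(u) {
    g <- try(mgcv::gam(u ~ te(x, y, bs = "bs", k = c(kx, ky)), data = dat),
             silent = TRUE)
    if (inherits(g, "try-error")) return(NULL)
    matrix(mgcv::predict.gam(g, newdata = grid), H, W, byrow = FALSE)
  }
  Rx <- fit_comp(dat$ux); Ry <- fit_comp(dat$uy)
  if (is.null(Rx) || is.null(Ry)) {
    warning("B-spline fit failed to converge; affine-only fallback")
    return(make_affine_field())
  }
  # compose: x -> A (x + r(x)) + t   (centered pixel coordinates)
  cy0 <- (H - 1) / 2; cx0 <- (W - 1) / 2
  xc <- matrix(rep(0:(W - 1) - cx0, each = H), H, W)
  yc <- matrix(rep(0:(H - 1) - cy0, W), H, W)
  A <- init$linear
  t_px <- init$translation_um / pixel_size_um
  xs <- xc + Rx; ys <- yc + Ry
  dx <- (A[1, 1] * xs + A[1, 2] * ys + t_px[1]) - xc
  dy <- (A[2, 1] * xs + A[2, 2] * ys + t_px[2]) - yc
  warped <- cpp_warp_bilinear(moving, dx, dy)
  sim <- ncc_inset(reference, warped, margin)
  if (sim < sim_affine) {
    warning("nonrigid stage did not improve similarity; affine-only fallback")
    return(make_affine_field())
  }
  fl <- deformation_field(dx * pixel_size_um, dy * pixel_size_um, frame)
  attr(fl, "similarity") <- sim
  fl
}

#' Estimate motion fields for a whole B-mode sequence
#'
#' @param bmode A B-mode [frame_sequence()].
#' @param method `"bspline"` (two-stage, default), `"affine"`, or `"none"`.
#' @param reference Index of the reference frame (default first frame).
#' @param control_spacing_px,search_px Nonrigid stage parameters.
#' @return List of [deformation_field()], one per frame (zero field for the
#'   reference frame).
#' @export
estimate_motion <- function(bmode, method = c("bspline", "affine", "none"),
                            reference = 1L, control_spacing_px = 16,
                            search_px = 4) {
  method <- match.arg(method)
  T <- n_frames(bmode)
  d <- dim(bmode$frames)[2:3]
  zero <- function(f) deformation_field(matrix(0, d[1], d[2]),
                                        matrix(0, d[1], d[2]), f)
  if (method == "none") return(lapply(seq_len(T), zero))
  ref <- get_frame(bmode, reference)
  px <- bmode$pixel_size_um
  fields <- vector("list", T)
  for (f in seq_len(T)) {
    if (f == reference) { fields[[f]] <- zero(f); next }
    mov <- get_frame(bmode, f)
    tf <- estimate_global_affine(ref, mov, px)
    if (method == "affine") {
      fl <- affine_to_field(tf, d, px, f)
      attr(fl, "similarity") <- attr(tf, "similarity")
      fields[[f]] <- fl
    } else {
      fields[[f]] <- estimate_nonrigid_bspline(ref, mov, tf, px,
                                               control_spacing_px, search_px,
                                               frame = f)
    }
  }
  fields
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `v(x) = -u(x + v(x))`; for the small, smooth motions
#' handled here 3 iterations suffice. With `iterations = 0` this is plain
#' negation.
#'
#' @param field A [deformation_field()] (um).
#' @param pixel_size_um Pixel pitch (um).
#' @param iterations Fixed-point iterations (default 3).
#' @return A [deformation_field()].
#' @export
invert_displacement_field <- function(field, pixel_size_um, iterations = 3) {
  vx <- -field$dx / pixel_size_um
  vy <- -field$dy / pixel_size_um
  ux <- field$dx / pixel_size_um
  uy <- field$dy / pixel_size_um
  for (i in seq_len(iterations)) {
    vx <- -cpp_warp_bilinear(ux, vx, vy)
    vy <- -cpp_warp_bilinear(uy, vx, vy)
  }
  deformation_field(vx * pixel_size_um, vy * pixel_size_um, field$frame,
                    field$fallback)
}

#' Apply reversed motion fields to the CEUS channel
#'
#' Resamples each CEUS frame at `x + u(x)` where `u` is that frame's
#' estimated reference-to-moving displacement, so scene content returns to
#' its reference-frame position and localized bubbles accumulate correctly.
#'
#' @param ceus A CEUS [frame_sequence()].
#' @param fields List of [deformation_field()], one per frame.
#' @return The corrected [frame_sequence()].
#' @export
correct_ceus <- function(ceus, fields) {
  T <- n_frames(ceus)
  if (length(fields) != T)
    stop_invalid("need exactly one deformation field per frame")
  d <- dim(ceus$frames)[2:3]
  px <- ceus$pixel_size_um
  out <- array(0, dim(ceus$frames))
  for (f in seq_len(T)) {
    fl <- fields[[f]]
    if (!all(dim(fl$dx) == d))
      stop_invalid("field shape does not match frame shape at frame ", f)
    out[f, , ] <- cpp_warp_bilinear(get_frame(ceus, f), fl$dx / px, fl$dy / px)
  }
  frame_sequence(out, px, ceus$frame_rate_hz, ceus$channel)
}

#' Export transforms as JSON
#'
#' @param transforms List of [affine_transform()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transforms_json <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(tf)
    list(linear = unclass(tf$linear), translation_um = tf$translation_um)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
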