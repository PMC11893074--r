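# Microbubble localization: sequence normalization, data-driven PSF
# estimation, upsampling to the fine reconstruction grid, and peak detection
# on the zero-normalized cross-correlation (ZNCC) coefficient map between
# each frame and the PSF.

#' Normalize a CEUS sequence by its global maximum
#'
#' @param ceus A [frame_sequence()].
#' @return The sequence divided by its sequence-wide maximum (new max = 1).
#' @export
normalize_sequence <- function(ceus) {
  m <- max(ceus$frames)
  if (m <= 0) stop_degenerate("all-zero sequence cannot be normalized")
  ceus$frames <- ceus$frames / m
  ceus
}

#' PSF model
#'
#' @param kernel Nonnegative 2D kernel on the fine grid, odd side lengths,
#'   max = 1 (centered).
#' @param sigma_um Length-2 Gaussian sigma estimates (x, y) in um.
#' @param fine_pixel_um Fine grid pitch (um).
#' @param parametric_fallback TRUE when too few isolated blobs were found
#'   and the kernel is a fitted parametric Gaussian.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(kernel, sigma_um, fine_pixel_um,
                      parametric_fallback = FALSE) {
  kernel <- as.matrix(kernel)
  if (nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0)
    stop_invalid("PSF kernel must have odd side lengths")
  if (sum(kernel) <= 0) stop_invalid("PSF kernel must have positive mass")
  kernel <- pmax(kernel, 0) / max(kernel)
  structure(list(kernel = kernel, sigma_um = sigma_um,
                 fine_pixel_um = fine_pixel_um,
                 parametric_fallback = parametric_fallback),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> %d x %d fine px, sigma ~ (%.1f, %.1f) um%s\n",
              nrow(x$kernel), ncol(x$kernel), x$sigma_um[1], x$sigma_um[2],
              if (x$parametric_fallback) " (parametric fallback)" else ""))
  invisible(x)
}

psf_fwhm_um <- function(psf) 2 * sqrt(2 * log(2)) * mean(psf$sigma_um)

gaussian_kernel_fine <- function(sigma_um, config, radius_factor = 2.5) {
  fp <- config$fine_pixel_um
  r <- as.integer(ceiling(radius_factor * sigma_um / fp))
  x <- (-r):r * fp
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma_um^2))
  k / max(k)
}

# least-squares Gaussian fit (amplitude, offset, sigma per axis) of a patch
# whose peak is at the patch center; returns sigma in fine px
fit_gaussian_sigma <- function(patch) {
  r <- (nrow(patch) - 1) / 2
  x <- (-r):r
  X <- matrix(rep(x, each = length(x)), length(x))
  Y <- t(X)
  obj <- function(p) {
    A <- p[1]; b <- p[2]; sx <- abs(p[3]); sy <- abs(p[4])
    mdl <- A * exp(-(X^2 / (2 * sx^2) + Y^2 / (2 * sy^2))) + b
    sum((mdl - patch)^2)
  }
  p0 <- c(max(patch) - min(patch), min(patch), r / 2, r / 2)
  o <- optim(p0, obj, method = "Nelder-Mead",
             control = list(maxit = 500, reltol = 1e-10))
  abs(o$par[3:4])
}

#' Estimate the PSF from isolated bright blobs in the data
#'
#' Takes the `n_samples` brightest local maxima of the (normalized) coarse
#' frames whose nearest other maximum is at least 3 patch radii away,
#' extracts a patch around each on the fine grid, recenters on the fine-grid
#' peak, and averages. Falls back to a parametric Gaussian fitted to the
#' single best blob if fewer than 5 isolated blobs are found (flagged).
#'
#' @param ceus A (normalized) CEUS [frame_sequence()].
#' @param n_samples Number of blob patches to average.
#' @param config An [acquisition_config()].
#' @param patch_radius_px Patch radius in coarse pixels.
#' @param intensity_floor Minimum blob intensity relative to the sequence
#'   max; maxima below it are treated as noise.
#' @param max_frames At most this many frames are scanned (evenly spaced).
#' @return A [psf_model()].
#' @export
estimate_psf <- function(ceus, n_samples = 30, config = NULL,
                         patch_radius_px = 5, intensity_floor = 0.35,
                         max_frames = 60) {
  if (is.null(config))
    config <- acquisition_config(pixel_size_um = ceus$pixel_size_um,
                                 frame_rate_hz = ceus$frame_rate_hz,
                                 duration_s = max(3 / ceus$frame_rate_hz,
                                                  n_frames(ceus) / ceus$frame_rate_hz),
                                 field_of_view = dim(ceus$frames)[2:3])
  ratio <- upsample_ratio(config)
  T <- n_frames(ceus)
  H <- dim(ceus$frames)[2]; W <- dim(ceus$frames)[3]
  gmax <- max(ceus$frames)
  if (gmax <= 0) stop_degenerate("empty sequence")
  # noise floor: relative to the global max, but never inside the bulk of
  # the intensity distribution (pure noise must yield no candidates)
  v <- as.vector(ceus$frames)
  thresh <- max(intensity_floor * gmax, median(v) + 6 * stats::mad(v))
  pr <- patch_radius_px
  frames_idx <- unique(as.integer(round(seq(1, T, length.out = min(T, max_frames)))))
  cand <- list()
  for (f in frames_idx) {
    fr <- get_frame(ceus, f)
    pk <- cpp_local_maxima(fr, thresh)
    if (nrow(pk) == 0) next
    # merge plateau duplicates (ties within 2 px) before the isolation test
    if (nrow(pk) > 1) {
      pk <- pk[order(-pk[, 3]), , drop = FALSE]
      keep_d <- rep(TRUE, nrow(pk))
      for (ii in seq_len(nrow(pk) - 1)) {
        if (!keep_d[ii]) next
        jj <- (ii + 1):nrow(pk)
        dd <- sqrt((pk[jj, 1] - pk[ii, 1])^2 + (pk[jj, 2] - pk[ii, 2])^2)
        keep_d[jj][dd <= 2] <- FALSE
      }
      pk <- pk[keep_d, , drop = FALSE]
    }
    # interior + isolation: nearest other maximum >= 3 patch radii
    keep <- pk[, 1] > pr & pk[, 1] <= H - pr & pk[, 2] > pr & pk[, 2] <= W - pr
    if (nrow(pk) > 1) {
      D <- as.matrix(stats::dist(pk[, 1:2, drop = FALSE]))
      diag(D) <- Inf
      keep <- keep & (apply(D, 1, min) >= 3 * pr)
    }
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk)) cand[[length(cand) + 1]] <-
      cbind(frame = f, pk)
  }
  cand <- if (length(cand)) do.call(rbind, cand) else NULL
  if (is.null(cand) || nrow(cand) == 0)
    stop_degenerate("no local maxima above the noise floor: cannot estimate PSF")
  cand <- cand[order(-cand[, 4]), , drop = FALSE]
  n_use <- min(n_samples, nrow(cand))
  fine_r <- pr * ratio
  acc <- matrix(0, 2 * fine_r + 1, 2 * fine_r + 1)
  used <- 0
  for (i in seq_len(n_use)) {
    f <- cand[i, 1]; r <- cand[i, 2]; c <- cand[i, 3]
    patch <- get_frame(ceus, f)[(r - pr):(r + pr), (c - pr):(c + pr)]
    fine <- cpp_bicubic_resize(patch, ratio)
    fine <- fine[1:(2 * fine_r + 1), 1:(2 * fine_r + 1)]
    # recenter on the fine-grid peak
    pkf <- which(fine == max(fine), arr.ind = TRUE)[1, ]
    sr <- pkf[1] - (fine_r + 1); sc <- pkf[2] - (fine_r + 1)
    if (abs(sr) > ratio || abs(sc) > ratio) next
    shifted <- cpp_warp_bilinear(fine, matrix(sc, nrow(fine), ncol(fine)),
                                 matrix(sr, nrow(fine), ncol(fine)))
    acc <- acc + shifted / max(shifted)
    used <- used + 1
  }
  fallback <- used < 5
  if (used > 0) {
    kern <- acc / used
    kern <- kern - stats::quantile(kern, 0.05)
    kern <- pmax(kern, 0)
    kern <- kern / max(kern)
  } else stop_degenerate("no usable blob patches for PSF estimation")
  sig_px <- fit_gaussian_sigma(kern)
  sigma_um <- sig_px * config$fine_pixel_um
  if (fallback) kern <- gaussian_kernel_fine(mean(sigma_um), config)
  psf_model(kern, sigma_um, config$fine_pixel_um, parametric_fallback = fallback)
}

#' Upsample a coarse frame to the fine reconstruction grid
#'
#' Corner-aligned bicubic (Catmull-Rom) spline interpolation: fine sample
#' `ratio*(k-1)+1` coincides with coarse sample `k`, and polynomial ramps
#' are reproduced exactly.
#'
#' @param frame 2D matrix on the coarse grid.
#' @param config An [acquisition_config()]; the coarse/fine ratio must be an
#'   integer.
#' @return Matrix of shape `ratio * dim(frame)`.
#' @export
upsample_to_fine <- function(frame, config) {
  ratio <- config$pixel_size_um / config$fine_pixel_um
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_invalid("coarse/fine pixel ratio must be an integer")
  cpp_bicubic_resize(frame, as.integer(round(ratio)))
}

# ZNCC coefficient map of a fine frame against the PSF kernel ("same" size;
# values in [-1, 1], computed with FFT numerator and box-sum denominator).
zncc_map <- function(fine_frame, kernel, plan = NULL) {
  K0 <- kernel - mean(kernel)
  ssK <- sum(K0^2)
  if (ssK <= 0) stop_invalid("flat PSF kernel")
  # ZNCC is invariant to affine intensity maps; centering the frame first
  # conditions the running-sum variance (s2 - s1^2/n) far better
  fine_frame <- fine_frame - mean(fine_frame)
  num <- fft_crosscorr(fine_frame, K0, plan)
  rh <- (nrow(kernel) - 1L) %/% 2L; rw <- (ncol(kernel) - 1L) %/% 2L
  n <- length(kernel)
  s1 <- box_sum(fine_frame, rh, rw)
  s2 <- box_sum(fine_frame^2, rh, rw)
  den <- sqrt(pmax(s2 - s1^2 / n, 0) * ssK)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-10] <- 0
  # no clamping here: roundoff plateaus at exactly 1 would break unique peak
  # detection; scores are clamped when reported.
  out
}

new_localizations <- function() {
  data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
             score = numeric())
}

#' Localize microbubbles in one fine-grid frame
#'
#' Computes the ZNCC coefficient map of the frame against the PSF, finds
#' local maxima above `threshold` with a minimum peak separation of one PSF
#' FWHM, and refines each peak by a quadratic fit to the 3x3 neighbourhood
#' of the coefficient map. Positions are in um (frame of reference of the
#' coarse grid; see package coordinate conventions).
#'
#' @param fine_frame Matrix on the fine grid.
#' @param psf A [psf_model()].
#' @param threshold Correlation-coefficient detection threshold in (0, 1).
#' @param config An [acquisition_config()].
#' @param frame Frame index recorded in the output.
#' @param plan Optional precomputed kernel FFT (internal speed-up used by
#'   [localize_sequence()]).
#' @return `data.frame(frame, x_um, y_um, score)`; empty when nothing is
#'   detected.
#' @export
localize_frame <- function(fine_frame, psf, threshold = 0.6, config,
                           frame = NA_integer_, plan = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop_invalid("threshold must lie in (0, 1)")
  cc <- zncc_map(fine_frame, psf$kernel, plan)
  pk <- cpp_local_maxima(cc, threshold)
  if (nrow(pk) == 0) return(new_localizations())
  # non-maximum suppression at one PSF FWHM
  min_sep_px <- psf_fwhm_um(psf) / config$fine_pixel_um
  ord <- order(-pk[, 3])
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      j <- (i + 1):nrow(pk)
      d <- sqrt((pk[j, 1] - pk[i, 1])^2 + (pk[j, 2] - pk[i, 2])^2)
      keep[j][d < min_sep_px] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  H <- nrow(cc); W <- ncol(cc)
  res <- matrix(0, nrow(pk), 3)
  for (i in seq_len(nrow(pk))) {
    r <- pk[i, 1]; c <- pk[i, 2]
    dr <- dc <- 0
    if (r > 1 && r < H) {
      den <- cc[r - 1, c] - 2 * cc[r, c] + cc[r + 1, c]
      if (den < 0) dr <- 0.5 * (cc[r - 1, c] - cc[r + 1, c]) / den
    }
    if (c > 1 && c < W) {
      den <- cc[r, c - 1] - 2 * cc[r, c] + cc[r, c + 1]
      if (den < 0) dc <- 0.5 * (cc[r, c - 1] - cc[r, c + 1]) / den
    }
    dr <- max(min(dr, 0.5), -0.5); dc <- max(min(dc, 0.5), -0.5)
    res[i, ] <- c(r + dr, c + dc, pk[i, 3])
  }
  data.frame(frame = frame,
             x_um = fine_to_um(res[, 2], config),
             y_um = fine_to_um(res[, 1], config),
             score = pmin(pmax(res[, 3], -1), 1))
}

#' Localize all frames of a (corrected, normalized) CEUS sequence
#'
#' Upsamples each frame to the fine grid and runs [localize_frame()]; the
#' kernel FFT is precomputed once.
#'
#' @param ceus A [frame_sequence()].
#' @param psf A [psf_model()].
#' @param config An [acquisition_config()].
#' @param threshold Detection threshold.
#' @return `data.frame(frame, x_um, y_um, score)` over all frames.
#' @export
localize_sequence <- function(ceus, psf, config, threshold = 0.6) {
  T <- n_frames(ceus)
  dims_fine <- dim(ceus$frames)[2:3] * upsample_ratio(config)
  plan <- fft_corr_plan(dims_fine, psf$kernel - mean(psf$kernel))
  out <- vector("list", T)
  for (f in seq_len(T)) {
    fine <- upsample_to_fine(get_frame(ceus, f), config)
    out[[f]] <- localize_frame(fine, psf, threshold, config, frame = f,
                               plan = plan)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write localizations to CSV
#'
#' @param localizations `data.frame(frame, x_um, y_um, score)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_localizations_csv <- function(localizations, path) {
  write.csv(localizations, path, row.names = FALSE)
  invisible(path)
}
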