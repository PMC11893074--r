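# Vascular morphometrics: the five per-acquisition readouts — tortuosity,
# fractal dimension, mean velocity, vessel density, mean vessel diameter —
# computed from tracks and the binarized ULM maps.

#' Trajectory tortuosity
#'
#' Ratio of the trajectory arc length to the distance between its two ends
#' (>= 1). Near-closed trajectories (endpoint distance below `eps_um`)
#' cannot be scored and return `NA`.
#'
#' @param track A track data.frame with `x_um`, `y_um` (or a 2-column
#'   matrix of points in um).
#' @param eps_um Minimum endpoint distance (default two fine pixels, 8 um).
#' @return Scalar tortuosity, or `NA` for an excluded track.
#' @export
tortuosity <- function(track, eps_um = 8) {
  P <- if (is.data.frame(track)) cbind(track$x_um, track$y_um)
       else as.matrix(track)
  if (nrow(P) < 2) return(NA_real_)
  arc <- sum(sqrt(rowSums(diff(P)^2)))
  chord <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  if (chord <= eps_um) return(NA_real_)
  arc / chord
}

#' Acquisition-level tortuosity
#'
#' Arithmetic mean of per-track tortuosities over scorable tracks.
#'
#' @param tracks An `ulm_tracks` object or list of tracks.
#' @param eps_um Passed to [tortuosity()].
#' @return List with `mean`, `per_track` and `n_excluded`.
#' @export
tortuosity_summary <- function(tracks, eps_um = 8) {
  v <- vapply(tracks, tortuosity, numeric(1), eps_um = eps_um)
  list(mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
       per_track = v, n_excluded = sum(is.na(v)))
}

box_count <- function(mask, s) {
  H <- nrow(mask); W <- ncol(mask)
  Hp <- ceiling(H / s) * s; Wp <- ceiling(W / s) * s
  M <- matrix(FALSE, Hp, Wp)
  M[1:H, 1:W] <- mask
  # fold rows into s-blocks, then columns
  A <- matrix(colSums(array(M, c(s, Hp / s * Wp))) > 0, Hp / s, Wp)
  B <- t(matrix(colSums(array(t(A), c(s, Wp / s * (Hp / s)))) > 0, Wp / s, Hp / s))
  sum(B)
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts occupied boxes `N(s)` over a scale ladder and returns the slope of
#' the least-squares fit of `log N(s)` against `log(1/s)`. The default
#' ladder is dyadic, `s in {1, 2, 4, ..., min(H, W)/4}`; for fit stability
#' up to the two largest scales are dropped when they hold fewer than 4
#' occupied boxes.
#'
#' @param mask Logical matrix; must contain at least one `TRUE`.
#' @param scales Optional integer vector of box sizes (overrides the dyadic
#'   ladder, e.g. powers of 3 for triadic constructions).
#' @return Fractal dimension with attribute `"fit"` (the per-scale table).
#' @export
fractal_dimension <- function(mask, scales = NULL) {
  if (!any(mask)) stop_degenerate("empty mask has no fractal dimension")
  if (is.null(scales)) {
    smax <- min(dim(mask)) / 4
    scales <- 2^(0:floor(log2(max(smax, 1))))
  }
  scales <- sort(unique(as.integer(scales)))
  N <- vapply(scales, function(s) box_count(mask, s), numeric(1))
  dropped <- 0
  while (length(N) > 3 && N[length(N)] < 4 && dropped < 2) {
    N <- N[-length(N)]; scales <- scales[-length(scales)]
    dropped <- dropped + 1
  }
  fit <- lm(log(N) ~ log(1 / scales))
  d <- unname(coef(fit)[2])
  attr(d, "fit") <- data.frame(scale = scales, N = N)
  d
}

#' Mean velocity over the vessel support
#'
#' Mean of velocity-map values over pixels with positive density (the
#' paper-style pixel average); `method = "tracks"` instead averages the
#' per-step speeds over all track samples.
#'
#' @param maps An [ulm_maps()] object.
#' @param tracks Optional `ulm_tracks`, required for `method = "tracks"`.
#' @param method `"pixels"` (default) or `"tracks"`.
#' @return Mean velocity (mm/s).
#' @export
mean_velocity <- function(maps, tracks = NULL,
                          method = c("pixels", "tracks")) {
  method <- match.arg(method)
  if (method == "tracks") {
    if (is.null(tracks)) stop_invalid("tracks required for method='tracks'")
    sp <- unlist(lapply(tracks, function(tr)
      sqrt(tr$vx_um_s^2 + tr$vy_um_s^2) / 1000))
    if (!length(sp)) stop_degenerate("no track samples")
    return(mean(sp))
  }
  support <- maps$density > 0
  if (!any(support)) stop_degenerate("empty vessel support")
  mean(maps$velocity[support])
}

#' Vessel density
#'
#' Fraction of the region of interest covered by the binarized vessel mask.
#'
#' @param mask Logical vessel mask.
#' @param roi Logical ROI of the same shape (default: whole field of view).
#' @return Fraction in \[0, 1\].
#' @export
vessel_density <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!any(roi)) stop_invalid("empty ROI")
  if (!all(dim(mask) == dim(roi))) stop_invalid("mask and ROI shapes differ")
  sum(mask & roi) / sum(roi)
}

# binary morphology via the exact distance transform
dilate_mask <- function(mask, r_px)
  cpp_edt(!mask, pad_background = FALSE) <= r_px
erode_mask <- function(mask, r_px) cpp_edt(mask) > r_px
close_mask <- function(mask, r_px) erode_mask(dilate_mask(mask, r_px), r_px)
open_mask <- function(mask, r_px) dilate_mask(erode_mask(mask, r_px), r_px)

# fill interior holes: background components not connected to the image
# border become foreground (a perforated lumen would otherwise draw the
# skeleton around every hole and bias the diameter far low)
fill_holes <- function(mask) {
  bg <- cpp_label(!mask)
  if (max(bg) == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  holes <- setdiff(seq_len(max(bg)), border)
  if (length(holes)) mask[bg %in% holes] <- TRUE
  mask
}

# iteratively peel skeleton endpoints (spur pruning); keeps >= 1 pixel
prune_skeleton <- function(skel, n_iter = 5) {
  for (i in seq_len(n_iter)) {
    nb <- box_sum(skel * 1, 1, 1) - skel
    endpoints <- skel & nb <= 1
    if (!any(endpoints)) break
    nxt <- skel & !endpoints
    if (!any(nxt)) break
    skel <- nxt
  }
  skel
}

#' Mean vessel diameter
#'
#' Skeletonizes the mask to 1-pixel centerlines (short spurs pruned), takes
#' at each skeleton pixel twice the Euclidean distance to the nearest
#' background pixel, and averages, in um.
#'
#' @param mask Logical vessel mask on the fine grid.
#' @param config An [acquisition_config()] (provides `fine_pixel_um`), or a
#'   numeric fine pixel pitch.
#' @param prune_px Spur-pruning iterations (default 5).
#' @param fill TRUE (default) fills interior holes before skeletonization.
#' @param regularize_px Radius (fine px) of the boundary regularization
#'   (morphological closing then opening) applied before skeletonization;
#'   default 2 px (8 um, the scale of the localization uncertainty). Rough
#'   edges otherwise spawn skeleton spurs that bias the diameter low. 0
#'   disables.
#' @return Mean diameter (um) with attribute `"n_skeleton_px"`.
#' @export
mean_diameter <- function(mask, config, prune_px = 5, fill = TRUE,
                          regularize_px = 2) {
  fp <- if (inherits(config, "acquisition_config")) config$fine_pixel_um
        else as.numeric(config)
  if (!any(mask)) stop_degenerate("empty mask")
  if (regularize_px > 0) {
    reg <- open_mask(close_mask(mask, regularize_px), regularize_px)
    if (any(reg)) mask <- reg  # tiny masks could vanish under opening
  }
  if (fill) mask <- fill_holes(mask)
  skel <- cpp_thin(mask)
  skel <- prune_skeleton(skel, prune_px)
  if (!any(skel)) stop_degenerate("empty skeleton")
  d <- cpp_edt(mask)
  vals <- 2 * d[skel] * fp
  out <- mean(vals)
  attr(out, "n_skeleton_px") <- sum(skel)
  out
}

#' Compute the five vascular metrics of an acquisition
#'
#' @param tracks An `ulm_tracks` object.
#' @param maps An [ulm_maps()] object.
#' @param config An [acquisition_config()].
#' @param roi Optional logical ROI on the fine grid.
#' @return Object of class `vasc_metrics`: tortuosity (mean over tracks),
#'   fractal_dimension, mean_velocity_mm_s, vessel_density,
#'   mean_diameter_um, n_tracks, n_localizations.
#' @export
compute_metrics <- function(tracks, maps, config, roi = NULL) {
  tor <- tortuosity_summary(tracks, eps_um = 2 * config$fine_pixel_um)
  mask <- maps$mask
  if (!is.null(roi)) mask <- mask & roi
  fd <- if (any(mask)) as.numeric(fractal_dimension(mask)) else NA_real_
  md <- if (any(mask)) as.numeric(mean_diameter(mask, config)) else NA_real_
  structure(list(
    tortuosity = tor$mean,
    fractal_dimension = fd,
    mean_velocity_mm_s = mean_velocity(maps),
    vessel_density = vessel_density(maps$mask, roi),
    mean_diameter_um = md,
    n_tracks = length(tracks),
    n_localizations = sum(vapply(tracks, nrow, integer(1)))),
    class = "vasc_metrics")
}

#' @export
print.vasc_metrics <- function(x, ...) {
  cat("<vasc_metrics>\n")
  cat(sprintf("  tortuosity        : %.4f\n", x$tortuosity))
  cat(sprintf("  fractal dimension : %.4f\n", x$fractal_dimension))
  cat(sprintf("  mean velocity     : %.4f mm/s\n", x$mean_velocity_mm_s))
  cat(sprintf("  vessel density    : %.4f\n", x$vessel_density))
  cat(sprintf("  mean diameter     : %.2f um\n", x$mean_diameter_um))
  cat(sprintf("  tracks / locs     : %d / %d\n", x$n_tracks, x$n_localizations))
  invisible(x)
}

#' Write metrics as JSON and CSV
#'
#' @param metrics A `vasc_metrics` object.
#' @param path_json,path_csv Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_metrics <- function(metrics, path_json = NULL, path_csv = NULL) {
  out <- unclass(metrics)
  if (!is.null(path_json))
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path_csv))
    write.csv(as.data.frame(out), path_csv, row.names = FALSE)
  invisible(c(path_json, path_csv))
}
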