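# End-to-end orchestration: frames -> motion correction -> normalization ->
# PSF estimation -> localization -> tracking -> maps -> metrics, plus
# configuration serialization and standard-format I/O.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis in one serializable object.
#'
#' @param acquisition An [acquisition_config()].
#' @param registration List: `method` ("bspline", "affine" or "none"),
#'   `reference` frame index, `control_spacing_px`, `search_px`.
#' @param detection List: `threshold` (NCC coefficient, default 0.6),
#'   `psf_samples`, `psf_patch_radius_px`, `intensity_floor`.
#' @param tracking List: `gate` (Mahalanobis radius), `sigma_acc_mm_s2`,
#'   `meas_sd_um`, `init_vel_sd_mm_s`, `min_length`.
#' @param smoothing List: `type` ("gaussian"/"disk"/"none") and `sigma_um`
#'   or `r_um`.
#' @param binarize List: `threshold` (`NULL` = adaptive half-height),
#'   `min_area_px`.
#' @param roi Optional logical ROI matrix on the fine grid (or `NULL`).
#' @param output_dir Optional output directory for maps/tracks/report.
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acquisition_config(),
                            registration = list(method = "bspline",
                                                reference = 1L,
                                                control_spacing_px = 16,
                                                search_px = 4),
                            detection = list(threshold = 0.6,
                                             psf_samples = 30,
                                             psf_patch_radius_px = 5,
                                             intensity_floor = 0.35),
                            tracking = list(gate = 3,
                                            sigma_acc_mm_s2 = 1,
                                            meas_sd_um = 4,
                                            init_vel_sd_mm_s = 5,
                                            min_length = 3L),
                            smoothing = list(type = "gaussian", sigma_um = 4),
                            binarize = list(threshold = NULL,
                                            min_area_px = 5),
                            roi = NULL, output_dir = NULL, seed = 1L) {
  structure(list(acquisition = acquisition, registration = registration,
                 detection = detection, tracking = tracking,
                 smoothing = smoothing, binarize = binarize, roi = roi,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (JSON)
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config` invisibly returns `path`;
#'   `read_pipeline_config` returns the restored [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$acquisition <- unclass(x$acquisition)
  x$roi_packed <- if (!is.null(x$roi))
    list(dim = dim(x$roi), which = which(x$roi)) else NULL
  x$roi <- NULL
  x$output_dir <- NULL  # run-local, kept out so reruns are bit-identical
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acq <- do.call(acquisition_config, x$acquisition)
  roi <- NULL
  if (!is.null(x$roi_packed) && length(x$roi_packed)) {
    roi <- matrix(FALSE, x$roi_packed$dim[1], x$roi_packed$dim[2])
    roi[x$roi_packed$which] <- TRUE
  }
  reg <- x$registration; reg$reference <- as.integer(reg$reference)
  trk <- x$tracking; trk$min_length <- as.integer(trk$min_length)
  bin <- x$binarize
  if (is.null(bin$threshold)) bin["threshold"] <- list(NULL)
  pipeline_config(acquisition = acq, registration = reg,
                  detection = x$detection, tracking = trk,
                  smoothing = x$smoothing, binarize = bin, roi = roi,
                  output_dir = x$output_dir, seed = x$seed)
}

#' Run the full ULM pipeline
#'
#' Stages, in order: motion estimation on B-mode, reversal onto CEUS,
#' normalization, PSF estimation, fine-grid localization, tracking, map
#' accumulation, metrics. Fully deterministic given the inputs and
#' configuration. With fewer than `min_length` frames no track can survive
#' and the metrics are flagged unavailable.
#'
#' @param bmode,ceus Same-geometry [frame_sequence()] pair.
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage messages to stderr.
#' @return Object of class `run_report`: `metrics` (or `NULL`), `counts`,
#'   `config`, `version`, `wall_time_s`, `flags`, and the intermediate
#'   products `maps`, `tracks`, `localizations`, `psf`.
#' @export
run_pipeline <- function(bmode, ceus, config = pipeline_config(),
                         verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (!all(dim(bmode$frames) == dim(ceus$frames)))
    stop_invalid("precondition violated: B-mode and CEUS channels must have ",
                 "the same length and geometry")
  acq <- config$acquisition
  T <- n_frames(ceus)
  say <- function(...) if (verbose) message("[ulmr] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  flags <- list()

  say("motion estimation (%s) on %d frames", config$registration$method, T)
  fields <- stage("motion_correction", {
    if (T < 2 || identical(config$registration$method, "none"))
      estimate_motion(bmode, "none")
    else estimate_motion(bmode, config$registration$method,
                         reference = config$registration$reference %||% 1L,
                         control_spacing_px =
                           config$registration$control_spacing_px %||% 16,
                         search_px = config$registration$search_px %||% 4)
  })
  flags$registration_fallbacks <-
    sum(vapply(fields, function(f) isTRUE(f$fallback), logical(1)))
  ceus_c <- stage("motion_correction", correct_ceus(ceus, fields))

  say("normalization")
  ceus_n <- stage("localization", normalize_sequence(ceus_c))

  say("PSF estimation")
  psf <- stage("localization",
               estimate_psf(ceus_n,
                            n_samples = config$detection$psf_samples %||% 30,
                            config = acq,
                            patch_radius_px =
                              config$detection$psf_patch_radius_px %||% 5,
                            intensity_floor =
                              config$detection$intensity_floor %||% 0.35))
  flags$psf_parametric_fallback <- psf$parametric_fallback

  say("localization at threshold %.2f", config$detection$threshold %||% 0.6)
  locs <- stage("localization",
                localize_sequence(ceus_n, psf, acq,
                                  threshold = config$detection$threshold %||% 0.6))
  say("%d localizations", nrow(locs))

  say("tracking")
  trk <- config$tracking
  tracks <- stage("tracking",
                  link_tracks(locs, acq$frame_rate_hz,
                              gate = trk$gate %||% 3,
                              sigma_acc_um_s2 = (trk$sigma_acc_mm_s2 %||% 1) * 1000,
                              meas_sd_um = trk$meas_sd_um %||% 4,
                              init_vel_sd_um_s = (trk$init_vel_sd_mm_s %||% 5) * 1000,
                              min_length = trk$min_length %||% 3L,
                              n_frames = T))
  say("%d tracks kept, %d discarded", length(tracks), attr(tracks, "n_discarded"))

  metrics <- NULL
  maps <- NULL
  if (length(tracks) > 0) {
    say("maps + metrics")
    maps <- stage("mapping", ulm_maps(tracks, acq, config$smoothing,
                                      config$binarize))
    metrics <- stage("morphometrics",
                     compute_metrics(tracks, maps, acq, config$roi))
  } else {
    flags$metrics_unavailable <- TRUE
    say("no tracks survive the minimum-length filter; metrics unavailable")
  }
  wall <- proc.time()[["elapsed"]] - t0
  report <- structure(list(
    metrics = metrics,
    counts = list(n_frames = T,
                  n_localizations = nrow(locs),
                  n_tracks_formed = attr(tracks, "n_formed"),
                  n_tracks_kept = length(tracks),
                  n_tracks_discarded = attr(tracks, "n_discarded")),
    config = config,
    version = as.character(utils::packageVersion("ulmr")),
    wall_time_s = wall,
    flags = flags,
    maps = maps, tracks = tracks, localizations = locs, psf = psf),
    class = "run_report")
  if (!is.null(config$output_dir)) write_run_outputs(report, config$output_dir)
  say("done in %.1f s", wall)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> ulmr %s: %d frames, %d localizations, %d tracks\n",
              x$version, x$counts$n_frames, x$counts$n_localizations,
              x$counts$n_tracks_kept))
  if (!is.null(x$metrics)) print(x$metrics)
  else cat("  metrics unavailable (no tracks)\n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Maps as float TIFF, localizations and tracks as CSV, the metrics and run
#' report as JSON, and the configuration echo. The report JSON deliberately
#' omits the wall time so reruns are bit-identical.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_run_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(report$maps))
    files <- c(files, write_maps(report$maps, dir))
  f <- file.path(dir, "localizations.csv")
  write_localizations_csv(report$localizations, f); files <- c(files, f)
  f <- file.path(dir, "tracks.csv")
  write_tracks_csv(report$tracks, f); files <- c(files, f)
  if (!is.null(report$metrics)) {
    files <- c(files, write_metrics(report$metrics,
                                    file.path(dir, "metrics.json"),
                                    file.path(dir, "metrics.csv")))
  }
  f <- file.path(dir, "config.json")
  write_pipeline_config(report$config, f); files <- c(files, f)
  rep_json <- list(counts = report$counts, version = report$version,
                   flags = report$flags,
                   metrics = if (!is.null(report$metrics))
                     unclass(report$metrics) else NULL)
  f <- file.path(dir, "report.json")
  jsonlite::write_json(rep_json, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Read a paired B-mode/CEUS acquisition
#'
#' Either a single side-by-side stack whose frames hold the two channels in
#' two columns (B-mode left, CEUS right, split at the midline) or two
#' separate same-shape TIFF stacks.
#'
#' @param path One file path (`layout = "side_by_side"`) or a length-2
#'   vector `c(bmode, ceus)` (`layout = "two_stacks"`).
#' @param layout `"side_by_side"` or `"two_stacks"`.
#' @param config An [acquisition_config()] supplying pixel size and frame
#'   rate.
#' @return `list(bmode = , ceus = )` of [frame_sequence()] objects.
#' @export
read_acquisition <- function(path, layout = c("side_by_side", "two_stacks"),
                             config = acquisition_config()) {
  layout <- match.arg(layout)
  if (layout == "side_by_side") {
    arr <- read_tiff_stack(path[1])
    W <- dim(arr)[3]
    if (W %% 2 != 0)
      stop_invalid("side-by-side stack must have even width, got ", W)
    bm <- arr[, , 1:(W / 2), drop = FALSE]
    ce <- arr[, , (W / 2 + 1):W, drop = FALSE]
  } else {
    if (length(path) < 2)
      stop_invalid("two_stacks layout needs c(bmode, ceus) paths")
    bm <- read_tiff_stack(path[1])
    ce <- read_tiff_stack(path[2])
    if (!all(dim(bm) == dim(ce)))
      stop_invalid("B-mode and CEUS stacks have different shapes")
  }
  list(bmode = frame_sequence(bm, config$pixel_size_um, config$frame_rate_hz,
                              "bmode"),
       ceus = frame_sequence(ce, config$pixel_size_um, config$frame_rate_hz,
                             "ceus"))
}

#' Two-vessel resolution sweep
#'
#' For each center-to-center separation, builds the two-vessel phantom,
#' renders it, runs the pipeline (no motion, hence no registration), takes
#' the density-map profile perpendicular to the vessels (averaged over the
#' central portion along the vessels), and tests whether it shows two local
#' maxima whose inter-peak minimum is below `dip_ratio` times the lower
#' peak. Also reports whether the coarse CEUS maximum-intensity-projection
#' profile shows two peaks at the same criterion.
#'
#' @param separations_um Separations to test (um).
#' @param config An [acquisition_config()] (the field of view should be a
#'   narrow horizontal strip).
#' @param seed Scene/noise seed.
#' @param dip_ratio Inter-peak dip criterion (default 0.8).
#' @param psf_sigma_um Rendering PSF sigma (um).
#' @param detection_threshold NCC detection threshold.
#' @return `data.frame(separation_um, resolved, n_peaks, dip_ratio,
#'   peak_sep_um, mip_resolved)` with attribute `"min_resolved_um"` (the
#'   smallest separation passing the test).
#' @export
resolution_sweep <- function(separations_um = c(60, 48, 40, 32, 28.5, 24, 20),
                             config = acquisition_config(field_of_view = c(24L, 32L),
                                                         duration_s = 10),
                             seed = 1L, dip_ratio = 0.8, psf_sigma_um = 100,
                             detection_threshold = 0.6) {
  pc <- pipeline_config(acquisition = config,
                        registration = list(method = "none"),
                        detection = list(threshold = detection_threshold,
                                         psf_samples = 30,
                                         psf_patch_radius_px = 5,
                                         intensity_floor = 0.35))
  rows <- list()
  for (sep in separations_um) {
    scene <- make_two_vessel_phantom(sep, config, seed = seed)
    rnd <- render_frames(scene, psf_sigma_um = psf_sigma_um,
                         noise_seed = seed + 1000L)
    rep <- run_pipeline(rnd$bmode, rnd$ceus, pc)
    yc_um <- fov_um(config)[1] / 2
    res <- if (is.null(rep$maps)) {
      list(resolved = FALSE, n_peaks = 0L, dip = NA_real_, sep = NA_real_)
    } else {
      profile_two_peak_test(rep$maps$density, config, yc_um, sep, dip_ratio,
                            fine = TRUE)
    }
    mipres <- profile_two_peak_test(mip(rnd$ceus), config, yc_um, sep,
                                    dip_ratio, fine = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      separation_um = sep, resolved = res$resolved, n_peaks = res$n_peaks,
      dip_ratio = res$dip, peak_sep_um = res$sep,
      mip_resolved = mipres$resolved)
  }
  out <- do.call(rbind, rows)
  passed <- out$separation_um[out$resolved]
  attr(out, "min_resolved_um") <- if (length(passed)) min(passed) else NA_real_
  out
}

# Cross-vessel profile test: average the map over the central 60% along x,
# window the profile around the two expected ridges, and require two local
# maxima (the two largest) with an inter-peak dip below dip_ratio times the
# lower peak; their separation must bracket the nominal one (x0.5 - x2).
profile_two_peak_test <- function(map, config, yc_um, sep_um, dip_ratio,
                                  fine = TRUE) {
  W <- ncol(map); H <- nrow(map)
  cidx <- max(1, round(0.2 * W)):round(0.8 * W)
  prof <- rowMeans(map[, cidx, drop = FALSE])
  ys <- if (fine) fine_to_um(seq_len(H), config) else coarse_to_um(seq_len(H), config)
  win <- abs(ys - yc_um) <= max(2 * sep_um, 3 * config$pixel_size_um)
  prof <- prof[win]; ys <- ys[win]
  n <- length(prof)
  if (n < 3 || max(prof) <= 0)
    return(list(resolved = FALSE, n_peaks = 0L, dip = NA_real_, sep = NA_real_))
  ispeak <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) prof[i - 1] else -Inf
    r <- if (i < n) prof[i + 1] else -Inf
    prof[i] > l && prof[i] >= r
  }, logical(1)))
  if (length(ispeak) < 2)
    return(list(resolved = FALSE, n_peaks = length(ispeak),
                dip = NA_real_, sep = NA_real_))
  top <- ispeak[order(-prof[ispeak])][1:2]
  top <- sort(top)
  dip <- min(prof[top[1]:top[2]])
  lower <- min(prof[top])
  psep <- abs(ys[top[2]] - ys[top[1]])
  ok <- dip < dip_ratio * lower && psep > 0.5 * sep_um && psep < 2 * sep_um
  list(resolved = ok, n_peaks = length(ispeak), dip = dip / lower, sep = psep)
}
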