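#' Acquisition configuration
#'
#' Geometry and timing of a B-mode/CEUS acquisition: the coarse pixel pitch
#' of the scanner grid, the fine pitch of the super-resolution reconstruction
#' grid, frame rate, duration, field of view and probe center frequency.
#' Defaults follow a linear-probe small-animal protocol: 32 um pixels at
#' 55 frames/s for 20 s with a 15 MHz probe, reconstructed on a 4 um grid.
#'
#' @param pixel_size_um Coarse pixel pitch (um).
#' @param fine_pixel_um Reconstruction grid pitch (um); must divide
#'   `pixel_size_um` exactly.
#' @param frame_rate_hz Acquisition frame rate (Hz).
#' @param duration_s Acquisition duration (s); `duration_s * frame_rate_hz`
#'   must allow at least 3 frames (the minimum track length).
#' @param field_of_view Integer `(height_px, width_px)` of the coarse grid.
#' @param center_frequency_mhz Probe center frequency (MHz), informational.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(pixel_size_um = 32, fine_pixel_um = 4,
                               frame_rate_hz = 55, duration_s = 20,
                               field_of_view = c(64L, 64L),
                               center_frequency_mhz = 15) {
  if (pixel_size_um <= 0 || fine_pixel_um <= 0)
    stop_invalid("pixel sizes must be positive")
  ratio <- pixel_size_um / fine_pixel_um
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_invalid("pixel_size_um must be an integer multiple of fine_pixel_um")
  if (frame_rate_hz <= 0) stop_invalid("frame_rate_hz must be > 0")
  if (duration_s * frame_rate_hz < 3)
    stop_invalid("duration_s x frame_rate_hz must allow at least 3 frames")
  if (length(field_of_view) != 2 || any(field_of_view < 1))
    stop_invalid("field_of_view must be (height_px, width_px), both >= 1")
  structure(list(pixel_size_um = pixel_size_um,
                 fine_pixel_um = fine_pixel_um,
                 frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s,
                 field_of_view = as.integer(field_of_view),
                 center_frequency_mhz = center_frequency_mhz),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> %d x %d px @ %g um (fine %g um), %g Hz, %g s\n",
              x$field_of_view[1], x$field_of_view[2], x$pixel_size_um,
              x$fine_pixel_um, x$frame_rate_hz, x$duration_s))
  invisible(x)
}

upsample_ratio <- function(config) {
  as.integer(round(config$pixel_size_um / config$fine_pixel_um))
}

n_frames_of <- function(config) {
  as.integer(floor(config$duration_s * config$frame_rate_hz))
}

# Coordinate conventions (used everywhere downstream):
#  - frames are matrices with rows = y (axial, downward), cols = x (lateral);
#  - coarse pixel (row r, col c), 1-based, has center ((c-0.5), (r-0.5)) *
#    pixel_size_um in (x, y);
#  - fine index f (1-based) lies at coarse 0-based coordinate (f-1)/ratio,
#    i.e. at (f-1)*fine_pixel_um + pixel_size_um/2 in um (corner-aligned
#    upsampling: fine sample ratio*(k-1)+1 coincides with coarse sample k).
coarse_to_um <- function(idx1, config) (idx1 - 0.5) * config$pixel_size_um
um_to_coarse <- function(um, config) um / config$pixel_size_um + 0.5
fine_to_um <- function(idx1, config)
  (idx1 - 1) * config$fine_pixel_um + config$pixel_size_um / 2
um_to_fine <- function(um, config)
  (um - config$pixel_size_um / 2) / config$fine_pixel_um + 1

fov_um <- function(config) config$field_of_view * config$pixel_size_um

#' Frame sequence container
#'
#' A time-ordered stack of 2D intensity frames with its geometry and timing.
#'
#' @param frames Numeric array `T x H x W` (or list of `H x W` matrices) of
#'   nonnegative finite intensities.
#' @param pixel_size_um Pixel pitch (um).
#' @param frame_rate_hz Frame rate (Hz).
#' @param channel `"bmode"` or `"ceus"`.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, pixel_size_um, frame_rate_hz,
                           channel = c("ceus", "bmode")) {
  channel <- match.arg(channel)
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    arr <- array(0, c(length(frames), d[1], d[2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] < 1)
    stop_invalid("frames must be a T x H x W array with T >= 1")
  if (!all(is.finite(frames))) stop_invalid("intensities must be finite")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz, channel = channel),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence:%s> %d frames of %d x %d @ %g um, %g Hz\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_um, x$frame_rate_hz))
  invisible(x)
}

get_frame <- function(seq, i) seq$frames[i, , ]

n_frames <- function(seq) dim(seq$frames)[1]

#' Maximum intensity projection
#'
#' Per-pixel maximum over all frames of a sequence: the diffraction-limited
#' baseline image against which the super-resolved map is compared.
#'
#' @param seq A [frame_sequence()].
#' @return A matrix of the per-pixel maxima.
#' @export
mip <- function(seq) {
  apply(seq$frames, c(2, 3), max)
}
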