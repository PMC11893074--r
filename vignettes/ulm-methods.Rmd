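---
title: "Methods: super-resolution microbubble imaging in ulmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-resolution microbubble imaging in ulmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Ultrasound localization microscopy treats each intravascular microbubble as
a point scatterer imaged through the system point spread function (PSF).
Although the PSF is hundreds of microns wide, the *center* of an isolated
bubble can be estimated to a few microns; accumulating thousands of such
localizations, linked over time into trajectories, reconstructs the vascular
bed far below the diffraction limit. `ulmr` implements this for 2D
B-mode/CEUS sequences at a coarse pixel pitch of 32 µm, 55 frames/s, with
reconstruction on a 4 µm grid.

The processing chain and its assumptions:

* **Motion correction** assumes tissue motion is smooth in space and time
  and visible in the B-mode channel. A global affine transform (normalized
  cross-correlation objective, FFT translation initializer, Nelder-Mead
  refinement) captures bulk motion; a nonrigid residual is then measured by
  block matching (integer search plus continuous NCC refinement per block)
  and interpolated to a dense field by a tensor-product B-spline surface
  (`mgcv::gam`, `te(x, y, bs = "bs")`). The composed mapping is
  `x -> A(x + r(x)) + t`. The field maps reference coordinates to
  moving-frame coordinates, so resampling the CEUS frame at `x + u(x)`
  *reverses* the motion. If the composed similarity does not beat the
  affine-only similarity the stage falls back to affine with a warning and
  a flag — on nearly-rigid frames this is the expected, honest outcome.
* **Localization** assumes bubbles are sparse enough that their PSFs rarely
  overlap. The sequence is normalized by its global maximum; a PSF is
  estimated as the recentered average of the brightest isolated blob
  patches (a parametric Gaussian fallback, flagged, covers blob-poor
  sequences); frames are upsampled by corner-aligned Catmull-Rom bicubic
  interpolation, which preserves coarse samples exactly and reproduces
  polynomial ramps; and bubbles are detected as local maxima of the
  zero-normalized cross-correlation map above a threshold, at least one PSF
  FWHM apart, with quadratic 3×3 sub-pixel refinement. ZNCC makes detection
  invariant to affine intensity scaling.
* **Tracking** uses a constant-velocity Kalman model per track. The pairing
  probability is the innovation's Gaussian density normalized by its
  maximum, `p = exp(-d²/2)` with `d` the Mahalanobis distance, so the
  pairing cost `1/p` is 1 for a perfect prediction. Track-to-detection
  assignment, augmented with birth and death options, is solved exactly by
  a shortest-augmenting-path (Jonker-Volgenant) routine; optimality is
  verified against brute-force enumeration in the test suite. Only strictly
  consecutive frames are paired (no gap closing), and tracks shorter than
  3 frames are discarded.
* **Maps** rasterize each trajectory as line segments on the fine grid
  (joining localizations keeps slow-frame-rate tracks connected, which the
  skeleton-based diameter needs), accumulate counts and velocity-vector
  sums per pixel, smooth with a Gaussian kernel, and binarize. Velocity and
  direction maps are the magnitude and angle (`atan2(vy, vx)`, x rightward,
  y downward) of the per-pixel vector mean.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| detection threshold | 0.6 (NCC coefficient) | safely above speckle-induced correlations at the default noise level, low enough for ≥95% per-bubble detection; monotonicity in the threshold is tested |
| PSF sigma (rendering) | 100 µm | of the order of the wavelength at 15 MHz (~103 µm) |
| process noise | 1 mm/s² white-noise acceleration | bubbles in 1–5 mm/s flow change velocity slowly between 18 ms frames |
| measurement noise R | (4 µm)² per axis | one fine pixel: the localization quantization scale |
| new-track velocity prior | sd 5 mm/s, zero mean | spans the 0–10 mm/s physiological range |
| Mahalanobis gate | 3 | 99.7% acceptance for a correct pairing |
| birth/death penalty | each `exp(gate²/2)/2` | birth + death together equal the pairing cost at the gate, so pairings worse than the gate lose |
| map smoothing | Gaussian, σ = 4 µm (1 fine px) | represents localization uncertainty |
| binarization | adaptive half-height (see below) | the paper-style absolute count threshold is exposed too |
| min component area | 5 fine px | rejects isolated spurious detections |
| B-spline control spacing | 16 coarse px (adapted down for small frames), 2-stage | unconstrained by the source method; typical for speckle tracking |

## The binarization threshold

No absolute threshold is stated for the density-map binarization. A fixed
count threshold makes the recovered vessel *width* depend strongly on
acquisition length and on the threshold itself (the smoothed density falls
off over ~±σ at the lumen edge). `ulmr`'s pipeline default instead uses a
half-height rule: threshold = 0.5 × median on-vessel density, with
"on-vessel" taken at the single-localization post-smoothing level. At an
edge blurred symmetrically by localization error and smoothing, the
half-height crossing sits at the true edge, so the recovered width is
unbiased to first order. `binarize_density()` itself keeps the absolute
threshold contract for users who want the raw rule.

## Mean vessel diameter

Centerlines are extracted by Zhang–Suen thinning and the diameter at each
skeleton pixel is twice the exact Euclidean distance to the nearest
background pixel. Two pre-processing steps stabilize this against
finite-sampling artifacts: interior holes (unsaturated pixels inside the
lumen) are filled, and the mask boundary is regularized by morphological
closing then opening with a 2-fine-px (8 µm) radius — the scale of the
localization uncertainty. Without these, boundary roughness spawns skeleton
spurs whose small distances bias the mean far low on wide vessels; both are
exposed as arguments. Endpoint peeling (5 iterations) prunes remaining
short spurs.

## Mean velocity

"Averaging values on the velocity map" is ambiguous between averaging map
pixels and averaging track samples; `ulmr` averages map pixels over the
support (`density > 0`), and `mean_velocity(..., method = "tracks")`
provides the track-sample average for comparison. The two agree within a
few percent on single-speed scenes.

## The synthetic world

The generator works in the post-beamforming video domain the analysis
itself consumes; it does not simulate acoustics. Its stated-world defaults:

* bubbles appear at vessel inlets as a per-frame Poisson process and advect
  along the centerline; the default flow profile is **plug** (all
  streamlines at the segment speed) so that recovered speeds are comparable
  to a single ground-truth value — a parabolic (Poiseuille) profile is
  available but then the mean transit speed is 2/3 of the peak;
* lateral position is uniform across the lumen with a small per-frame
  jitter (0.5–2 µm), which is what lets long acquisitions fill the lumen;
* the CEUS channel renders each bubble as an isotropic Gaussian of σ =
  100 µm with per-track amplitudes uniform in [0.8, 1.2], over a Rayleigh
  speckle background at level 0.05 (≈26 dB bubble SNR) — chosen once so
  that localization at the default threshold succeeds for ≥95% of isolated
  bubbles, and exposed in `render_frames()`;
* the B-mode channel is a fixed PSF-correlated Rayleigh speckle texture
  warped by the tissue motion (global sinusoid plus a smooth zero-mean
  nonrigid pattern bounded by its amplitude), with the true fields retained
  for oracle comparisons;
* everything is bit-reproducible given the scene and noise seeds.

What a green test does **not** establish: performance under real acoustic
phenomena (nonlinear bubble oscillation, attenuation, shadowing,
out-of-plane motion), under bubble concentrations high enough that PSFs
overlap chronically, or on log-compressed export pipelines whose intensity
mapping differs from the simulated linear one. Scenes for the quantitative
recovery tests deliberately keep vessel endpoints ≥2.5 PSF σ inside the
field of view: blobs truncated by the image border localize with an inward
bias, which is a property of any bounded acquisition, not of the method.

## Numerical choices

* Upsampling is corner-aligned (fine sample `8(k-1)+1` equals coarse sample
  `k`) with a linearly extrapolated 2-px border, so linear ramps are exact
  to machine precision everywhere. Positions map as
  `x_um = 4(f-1) + 16` for 1-based fine index `f`.
* The ZNCC numerator is computed by FFT (padded to 2-3-5-smooth sizes) and
  the denominator by integral-image box sums; the frame is mean-centered
  first to avoid catastrophic cancellation in the running variance. The
  coefficient map is *not* clamped to [-1, 1] before peak finding — round-off
  plateaus at exactly 1 would defeat unique-peak detection — scores are
  clamped on report.
* Sub-pixel refinement clamps the quadratic offset to ±0.5 px and only
  applies it where the second difference is negative.
* The PSF estimator's noise floor is the larger of a fraction (0.35) of the
  global maximum and `median + 6·MAD` of the intensity distribution, so a
  pure-noise sequence produces no candidate blobs and errors out instead of
  averaging noise peaks.
* Assignment uses a large finite cost (1e12) instead of infinity for
  gated-out pairs; ties resolve deterministically by lowest row index.
* Field inversion (`invert_displacement_field()`) is a 3-iteration fixed
  point; plain negation is the 0-iteration special case. The pipeline's
  correction path needs neither: the estimated field already maps reference
  to moving coordinates.
* With fewer than 3 frames no track can pass the length filter; the report
  then carries `metrics_unavailable` instead of fabricating numbers.
* The run report's wall time is logged but excluded from the report JSON so
  that reruns of the same configuration are bit-identical.

## Design choices where the method was open

* *Reference frame*: the first frame (any frame works; relative geometry is
  reference-invariant, which the motion tests verify via corrected B-mode
  correlation).
* *Similarity metric*: normalized cross-correlation in both registration
  stages — robust for mono-modal speckle.
* *PSF estimation*: once per acquisition, not per frame; isolation
  criterion of 3 patch radii; plateau duplicates (bubbles centered on pixel
  corners) are merged before the isolation test.
* *p normalization*: the pairing probability is the likelihood normalized
  by its maximum rather than the raw density, bounding the cost below by 1
  and making birth/death penalties unit-free.
* *Smoothing before binarization*, not after.
* *Tortuosity aggregation*: arithmetic mean over scorable tracks;
  trajectories whose endpoints are closer than 2 fine px are excluded as
  near-closed (their ratio is numerically unstable) and counted in
  `n_excluded`.
* *Box-counting ladder*: dyadic by default, capped at min(H, W)/4, with up
  to the two largest scales dropped when they hold fewer than 4 occupied
  boxes; a custom ladder (e.g. powers of 3 for triadic fixtures) can be
  passed.
* *Config format*: JSON (human-readable, exact round-trip) — no YAML/TOML
  parser is available in the supported dependency set.
* *AVI ingestion is out*: no codec is available to R here; the side-by-side
  two-column layout is supported on TIFF stacks, and the package carries a
  minimal uncompressed grayscale TIFF reader/writer (verified against an
  independent implementation) because no R TIFF package is available
  either.

## Known limitations

* Bubbles closer than the Rayleigh limit within one frame are not
  separated (no deconvolution); dense scenes bias localizations between
  bubbles — the acceptance scenes use paper-scale sparse infusions.
* Vessel filling saturates slowly: diameter estimates need acquisitions
  long enough that streamlines cover the lumen (the 20 s protocol works for
  ≤160 µm vessels at the default rates).
* No gap closing across missed detections, by design (2-frame pairing).
* Single 2D plane: out-of-plane motion and 3D vessels are out of scope.
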