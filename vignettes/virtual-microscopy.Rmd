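---
title: "Virtual automated microscopy: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual automated microscopy: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtuscope)
```

virtuscope packages the computational side of an automated, motorized
brightfield microscope — autofocus, knife-edge resolution measurement,
distortion and lens-shading calibration, and autofocus-aware tile scanning
with stitching — together with a seeded virtual instrument on which every
one of those computations can be exercised end to end. This vignette
explains the models behind the simulator, the estimators built on top of
it, and the design decisions that were genuinely open, so that a user can
judge what a passing test suite does and does not demonstrate about a real
instrument.

## The virtual instrument

### Stage

The stage models a stepper-driven flexure positioner. Its parameters are
the actuator step sizes (defaults 70 nm in x and y, 50 nm in z), the
travel (12 x 12 x 4 mm), a per-axis backlash in steps, and a slow drift
rate in nm per hour. Commanded positions are quantized to whole steps with
round-half-to-even, the same rule R's `round()` uses; nm coordinates are
measured from the centre-of-travel step so that the origin is exactly
representable. Targets beyond the travel clamp and set a flag rather than
erroring, since that is what a real motion controller does.

Backlash is modelled as an asymmetric mechanical-play element: the
physical position `p` tracks the commanded position `c` under the
constraint `c - B <= p <= c` (in steps). Moving in one direction the
mechanism lags by up to `B` steps; on reversal, up to `B` steps of
commanded motion are absorbed before the physical position moves again. A
symmetric dead band of half-width `B/2` would have been an equally
defensible choice; the asymmetric form was chosen because it makes
"approach from a fixed direction" — the standard backlash-control
technique that the autofocus and z-stack routines use — exactly
reproducible: any target approached from below settles at the same
physical offset.

Drift is a deterministic linear offset of the physical position,
`rate * elapsed_hours` per axis, accumulated by the instrument clock. It
is deliberately simple: the purpose is to give time-lapse focus tracking
something realistic to fight (flexure mechanisms drift by tens of microns
over days), not to model creep physics.

### Optics and image formation

Image formation is intentionally the simplest model that preserves the
behaviours the calibrations measure:

* The in-focus amplitude point spread function is a Gaussian described by
  its full width at half maximum (`psf_fwhm_nm`, 480 nm for the 0.65 NA
  dry preset at a 100 nm sample-plane pixel pitch).
* Defocus adds blur linearly: at a distance `dz` from the focal surface
  the blur FWHM is `psf_fwhm_nm + defocus_blur_coeff * dz`. The default
  coefficient of 0.5 makes roughly 1 um of defocus double the in-focus
  width, a plausible proxy for a 0.65 NA objective's depth response. The
  linear-in-FWHM form is monotone and analytically convenient; no claim
  of aberration realism is made.
* In the default `coherent` edge model the specimen's *amplitude* (the
  square root of its transmittance) is convolved with the PSF and the
  result squared. This is the image-formation assumption under which the
  knife-edge estimator's square-root step exactly converts intensity back
  to amplitude. An `incoherent` mode (intensity convolved directly) is
  provided for sensitivity experiments.
* Vignetting multiplies the image by `1 - (1 - falloff) * r^2` with r
  normalized to 1 at the sensor corner, so the corner intensity is exactly
  `vignetting_falloff` (default 0.7) times the centre.
* Radial distortion maps an object point at normalized radius r to an
  image radius `r * (1 + k * r^2)` (r = 1 at the half-diagonal); the
  renderer inverts this per pixel by fixed-point iteration.
* The sensor is 8-bit with Gaussian read noise (default sigma 1 count)
  and a square-root signal-dependent term
  (`shot_noise_scale * sqrt(counts)`, default scale 0.2, about 3 counts
  at bright exposure) — a realistic signal-to-noise for a small CMOS
  sensor at base gain. Noise is applied last and is reproducible from an
  integer seed; with noise off, rendering is bit-reproducible.
* Every frame is JPEG-encoded once (really encoded, via libjpeg) at the
  camera's `compression_quality`, and the byte count is stored on the
  frame. The size-sharpness correlation that the fast autofocus exploits
  is therefore emergent, not scripted.

Specimen boundaries are softened over exactly one pixel pitch at render
time. This approximates the pixel-aperture integral that a real sensor
performs; without it, point-sampling a sharp boundary aliases its
sub-pixel position to the pixel grid, which quietly corrupts every
sub-pixel measurement downstream (we found this as structured,
phase-of-pixel residuals in the distortion scan).

The default sensor is 820 x 616 pixels — a scaled-down stand-in for an
8-megapixel 3280 x 2464 chip that keeps the test suite fast; the full
size is available through `camera_config()`. Tests use even smaller
sensors where only geometry is at stake.

### Specimens

Four analytic specimen types cover the calibrations: a flat field
(shading), a knife edge with adjustable tilt (resolution and distortion),
a periodic grid (pixel-size calibration), and a blood-smear-like field of
disks for focusing and scanning. The smear deserves comment because it
sets the study conditions for autofocus. Cells are disks of radius
~3.75 um at 8000 per mm^2 (a realistic well-spread monolayer, about a
third surface coverage), each with a brighter biconcave centre and —
critically — a band-limited "stain granularity" texture: a fixed, seeded
sum of 32 random plane waves with wavelengths around 1.2 um and amplitude
0.18. Real stained smears are full of sub-micron, high-contrast detail;
perfectly smooth discs are not, and no image-based focus metric can lock
onto them at realistic noise levels. The texture is a pure function of
slide coordinates, so it behaves correctly under stage motion, defocus
and stitching.

The in-focus height of the slide is a plane `z = a*x + b*y + c`, which
models slide tilt; it is the ground truth that autofocus accuracy is
measured against.

## Autofocus

`laplacian_sharpness()` is the classic focus metric: the mean squared
response of the 3x3 discrete Laplacian over valid pixels, on luminance.
`autofocus_sweep()` steps through the z range (always approached from
below, so backlash is taken up consistently), scores each frame, and
refines the peak with a parabola through the three samples around the
arg-max; a peak at either end of the range sets `at_boundary` and skips
refinement, because extrapolating a vertex outside the sampled range is
guesswork.

One deliberate choice: the sweep scores a 4x4 block-binned copy of each
frame (`preview_binning`). Camera pipelines run focus metrics on the
downscaled preview stream, and the reason becomes obvious in simulation:
the Laplacian of i.i.d. sensor noise has mean square `20 * sigma^2`
regardless of focus, a floor that at full resolution dwarfs the in-focus
signal of any honest specimen. Binning averages the noise down and moves
specimen detail toward the Nyquist frequency, where the Laplacian kernel
responds most strongly. With binning the sharpness-versus-z curve on the
default smear is cleanly unimodal; without it the same curve is barely
distinguishable from its noise floor. Set `preview_binning = 1` to see
that behaviour.

`jpeg_fast_autofocus()` implements the video-stream variant: the stage
moves through the range in one continuous pass while frames stream, and
the compressed byte size of each frame stands in for sharpness. The size
series is checked for flatness on the raw bytes (a featureless scene
gives "no focus found"; flatness is judged before smoothing because a
genuine focus peak spans only a few frames at practical scan speeds),
smoothed with a centred moving average (window 3), and the peak frame is
mapped to z through the constant-velocity model
`z = z0 + speed * (t_peak - t0 - latency)`. The camera-latency offset
defaults to 0 and is exposed because real pipelines delay frames by an
unknown amount. The method's advantage is structural: one continuous pass
instead of n settled moves, which is where its order-of-magnitude speed
advantage on real hardware comes from; wall-clock speed itself is not
something the simulator can honestly assert.

`execute_scan()` runs per-site autofocus as a coarse sweep followed by a
fine sweep spanning ±1.5 coarse spacings around the coarse peak. A single
sweep wide enough to be robust against slide tilt cannot also place focus
within the depth-of-focus proxy (the defocus that raises blur FWHM by
10%, under 100 nm for the default preset); the two-pass scheme achieves
both, which is also how practical instruments behave. A failed or
boundary-flagged autofocus flags the site and falls back to a plane fit
through previously focused sites — the same thin-flat-sample assumption
that justifies image autofocus in the first place — so a scan survives
occasional blank fields.

## Knife-edge resolution estimation

`extract_edge_profile()` implements the slanted-edge method. Every row's
edge crossing is located, rows are shifted to a common origin and pooled;
a 1-degree tilt makes the per-row crossings sweep through sub-pixel
phases, so the pooled samples oversample the edge profile far below the
pixel pitch. Two estimator details matter:

* The per-row location uses the *centroid of the intensity derivative*
  in a small window around the 50% crossing (the crossing itself still
  decides whether a row is usable, and rows without a clean monotone
  crossing count toward the "edge not detected" threshold of 20%).
  Linear interpolation of the 50% level — the more obvious choice — is
  piecewise-linear in the true edge position and quantizes to ~0.5 px
  plateaus on steep 8-bit edges; the derivative centroid varies smoothly
  and is the standard practice in slanted-edge MTF tools.
* The pooled samples are averaged into quarter-pixel bins (weighted by
  count) before a smoothing spline is fit with generalized
  cross-validation. Fitting tens of thousands of raw noisy points made
  GCV undersmooth systematically: the resulting ripple inflated the peak
  of the differentiated profile and biased the measured FWHM several
  percent low. Binning first lets GCV see the profile shape rather than
  the per-pixel noise. `spar` can be overridden when the automatic choice
  is unsuitable.

`psf_from_edge()` converts intensity to amplitude by square root — after
undoing the [0, 1] normalization with the stored dark/bright plateau
ratio, because `sqrt(normalized intensity)` is *not* the normalized
amplitude when the dark side of a real edge is not perfectly black — then
differentiates and reads off the FWHM by linear interpolation of the
half-maximum crossings, taking the outermost crossing on each side when
noise produces several. On the default coherent simulator at 100 nm/px
the recovered width is within ~3% of the configured 480 nm with noise on,
and the estimate scales linearly with the configured width from 300 to
1000 nm. Below roughly twice the pixel pitch the estimate degrades toward
a sampling floor — it is still reported, and should simply not be trusted
as a resolution figure there.

`sampling_check()` encodes the Bayer bookkeeping: a colour mosaic makes
the effective sampling unit a 2x2 pixel block, so 100 nm pixels sample at
an effective 200 nm, comfortably finer than a 480 nm PSF.

## Distortion

Because the optics are axisymmetric, distortion must be too, so a single
radial coefficient suffices: an object point at normalized radius r
appears at `r * (1 + k * r^2)`. `measure_distortion_scan()` translates a
vertical knife edge to several positions across the field (a straight
line should appear straight only through the centre), detects the edge in
every row, and `estimate_distortion()` fits k jointly with the unknown
per-line positions by alternating least squares. The k-regression is
centred within each line: a line's own offset parameter absorbs the mean
displacement, so only the bow *along* the line carries information about
k — an uncentred regression is biased tens of percent low. The reported
figure of merit is the worst-case displacement across the field as a
percentage of field width (`100 * |k| * r_halfdiag / width`). On the
distortion-free default system the full pipeline reports well below
0.05%; recovery of injected coefficients is linear with unit slope within
5% over the ±3% displacement range.

## Lens shading

`build_shading_table()` reduces a flat-field image to a coarse grid of
cell means (default 32 x 24, the granularity of hardware shading tables)
per channel and stores the ratio of the brightest cell to each cell, so
the minimum gain is exactly 1. `apply_shading_correction()` interpolates
the grid bilinearly to full resolution, multiplies, clips at the 8-bit
ceiling and reports the clip count. Cells darker than 5% of the brightest
abort calibration ("insufficient illumination") rather than produce
extreme gains.

Flatness after correction is judged by `flatness_rms()`: the RMS of
coarse cell means about the global mean. Per-pixel RMS would conflate
sensor noise with shading — the gain table corrects the low-frequency
vignetting field and *amplifies* pixel noise where gains exceed 1 (the
corner-noise cost of shading correction, which one test verifies
directly), so low-frequency flatness is the quantity the calibration can
and should control. Build-then-apply on independent noise realizations
flattens the default 0.7-falloff field to well under 1% RMS.

## Pixel-size calibration

`calibrate_pixel_size()` measures the dominant period of a grid target
from the mean row autocorrelation (computed via FFT with zero padding),
refines the first prominent peak with a parabola, and divides the known
pitch by the measured period. The field of view follows as sensor
dimensions times the distance-per-pixel; at the full 3280 x 2464
resolution and ~106.7 nm/px this reproduces a 350 um x 263 um field.

## Scanning and stitching

`plan_grid_scan()` lays out sites spaced `fov * (1 - overlap)` in snake
order (raster is available; the suite verifies snake strictly shortens
commanded travel on any multi-row grid), each carrying z-stack offsets
centred on 0. `execute_scan()` moves, focuses per policy, and captures
stacks with offsets applied relative to the found focus, every z
approached from below. Time-lapse plans are single-site plans with
scheduled capture times; the clock (and therefore drift) advances while
the plan waits.

`stitch_tiles()` registers adjacent tiles by phase correlation of their
nominal overlap regions (mean-subtracted and Hann-windowed), solves for
global positions by least squares over the pairwise-offset graph anchored
at the first tile, and composites the *central crop* of each tile
(default margin 25% per side) — tile edges carry the worst optics and are
used only for alignment. Pairs whose correlation peak falls below the
threshold (default 0.1) fall back to their nominal offsets and are
flagged rather than silently trusted. Registration is integer-pixel by
design: the acceptance bar is 1 px, and sub-pixel compositing would
require resampling the tiles.

Two properties pin the stitcher down: with zero noise and aligned
geometry (tile spacing commensurate with both the 70 nm step and the
100 nm pixel) the mosaic is bit-identical to a single large render of the
same region; and with whole-pixel placement jitter the recovered offsets
match the true stage positions to within a pixel while the manifest
claims only the nominal grid.

## Problem sizes and reproducibility

The test suite runs everything at reduced scale — sensors from 80 x 60 to
600 x 450 pixels, 2x2 to 3x3 grids, 4-frame time-lapses — chosen so the
full suite completes in about a minute while every estimator still
operates in its intended regime (the knife-edge pipeline, for instance,
pools several hundred rows). The acceptance script uses the default
820 x 616 sensor. Every stochastic path is reproducible from one integer
seed: the instrument derives a per-frame seed from (instrument seed,
frame counter), and seeded runs write byte-identical JSON reports.

## Known limitations

* The optics are Gaussian by construction: no Airy rings, aberrations,
  field curvature or chromatic effects. The 480 nm figure is an input the
  estimator must recover, not a diffraction calculation from NA.
* The linear defocus-blur model exaggerates nothing but also hides
  asymmetric through-focus behaviour; autofocus results should be read as
  algorithmic correctness, not optical fidelity.
* Bayer simulation is mosaic + bilinear demosaic only.
* The stage has no velocity profile; continuous motion is constant
  velocity, which is exactly the model the fast autofocus inverts, so the
  simulator cannot probe errors in that assumption (the configurable
  latency offset exists for that reason).
* Drift is linear and deterministic; real flexure drift is nonlinear in
  time and temperature.
* Simulated wall-clock time (settle times, frame intervals) supports
  relative comparisons only; no real-time performance claims follow.
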