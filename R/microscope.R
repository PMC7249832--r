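#' Assemble a virtual microscope
#'
#' Binds a stage, optics, specimen and camera into a single instrument with
#' a clock. The microscope is a mutable object (an environment): moving the
#' stage or capturing a frame advances time, applies stage drift for the
#' elapsed interval, and draws per-frame noise seeds from the instrument
#' seed, so a whole acquisition is reproducible from its configuration and
#' one integer.
#'
#' @param specimen a [specimen_field()].
#' @param optics an [optics_config()] (default: the 0.65 NA dry preset).
#' @param camera a [camera_config()].
#' @param stage a [stage_state()].
#' @param seed instrument seed; frame `i` of the session uses a seed
#'   derived from it.
#' @param settle_time_s time charged for each discrete stage move.
#' @return an object of class `vs_microscope`.
#' @export
#' @examples
#' mic <- virtual_microscope(specimen_flat(0.9))
#' fr <- mic_capture(mic)
#' range(fr$pixels)
virtual_microscope <- function(specimen,
                               optics = optics_preset("0.65NA-dry"),
                               camera = camera_config(),
                               stage = stage_state(),
                               seed = 1L,
                               settle_time_s = 0.2) {
  stopifnot(inherits(specimen, "vs_specimen"))
  mic <- new.env(parent = emptyenv())
  mic$specimen <- specimen
  mic$optics <- optics
  mic$camera <- camera
  mic$stage <- stage
  mic$seed <- as.integer(seed)
  mic$settle_time_s <- settle_time_s
  mic$frame_count <- 0L
  mic$time_s <- 0
  class(mic) <- "vs_microscope"
  mic
}

#' Advance the instrument clock
#'
#' Accumulates stage drift for the elapsed interval.
#' @param mic a [virtual_microscope()].
#' @param dt_s elapsed seconds.
#' @return the microscope, invisibly.
#' @export
mic_advance_time <- function(mic, dt_s) {
  stopifnot(inherits(mic, "vs_microscope"), dt_s >= 0)
  mic$time_s <- mic$time_s + dt_s
  mic$stage <- apply_drift(mic$stage, dt_s / 3600)
  invisible(mic)
}

#' Move the microscope stage
#'
#' @param mic a [virtual_microscope()].
#' @param target_nm named per-axis absolute target in nm (see [move_to()]).
#' @param settle charge the settle time to the clock (discrete moves);
#'   `FALSE` for continuous-motion sampling where the caller manages time.
#' @return the microscope, invisibly.
#' @export
mic_move <- function(mic, target_nm, settle = TRUE) {
  stopifnot(inherits(mic, "vs_microscope"))
  mic$stage <- move_to(mic$stage, target_nm)
  if (isTRUE(settle)) mic_advance_time(mic, mic$settle_time_s)
  invisible(mic)
}

#' Capture a frame
#'
#' Advances the clock by one frame interval (`1 / fps`), applies drift, and
#' renders at the current physical stage position with a per-frame seed.
#'
#' @param mic a [virtual_microscope()].
#' @return a `vs_frame` (see [render_frame()]).
#' @export
mic_capture <- function(mic) {
  stopifnot(inherits(mic, "vs_microscope"))
  mic_advance_time(mic, 1 / mic$camera$fps)
  mic$frame_count <- mic$frame_count + 1L
  render_frame(
    mic$stage, mic$optics, mic$specimen, mic$camera,
    seed = child_seed(mic$seed, mic$frame_count),
    timestamp_s = mic$time_s
  )
}

#' Current stage position of a microscope
#'
#' @param mic a [virtual_microscope()].
#' @param which `"physical"` or `"commanded"` (see [stage_position_nm()]).
#' @return named per-axis vector in nm.
#' @export
mic_position <- function(mic, which = "physical") {
  stage_position_nm(mic$stage, which)
}

#' @export
print.vs_microscope <- function(x, ...) {
  cat("<vs_microscope>\n")
  cat(sprintf(
    "  sensor: %d x %d px, pitch %g nm, PSF FWHM %g nm (%s)\n",
    x$camera$sensor_px[["width"]], x$camera$sensor_px[["height"]],
    x$optics$pixel_pitch_nm, x$optics$psf_fwhm_nm, x$optics$edge_model
  ))
  p <- mic_position(x)
  cat(sprintf(
    "  stage (nm): x=%.0f y=%.0f z=%.0f; t=%.2f s; %d frame(s)\n",
    p["x"], p["y"], p["z"], x$time_s, x$frame_count
  ))
  invisible(x)
}
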