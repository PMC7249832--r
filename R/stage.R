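#' Motorized three-axis stage state
#'
#' Models a stepper-driven flexure stage: commanded positions are quantized
#' to whole actuator steps (70 nm in x and y, 50 nm in z by default), travel
#' is limited (12 x 12 x 4 mm by default), reversing direction loses up to
#' `backlash_steps` of motion per axis, and the mechanism can drift slowly
#' over time independent of commanded moves.
#'
#' Coordinates are expressed in nm with the origin at the centre of travel,
#' x to the right and y up in the rendered image. Internally step counts run
#' from 0 at one end of travel to `travel_nm / step_size_nm` at the other,
#' so `0 <= steps * step_size_nm <= travel_nm` always holds.
#'
#' @param position_nm initial commanded position, named per-axis vector in
#'   nm (centre-of-travel origin). Defaults to the origin.
#' @param step_size_nm actuator step size per axis in nm.
#' @param travel_nm total travel per axis in nm.
#' @param backlash_steps non-negative lost motion per axis, in steps, taken
#'   up when the direction of travel reverses.
#' @param drift_rate_nm_per_hour slow mechanical drift per axis; applied by
#'   [apply_drift()], typically via the simulator clock.
#' @return an object of class `vs_stage`.
#' @seealso [move_to()], [apply_drift()], [stage_position_nm()]
#' @export
#' @examples
#' st <- stage_state()
#' st <- move_to(st, c(z = 105))
#' stage_position_nm(st)["z"] # quantized to 100 nm (2 steps of 50 nm)
stage_state <- function(position_nm = c(x = 0, y = 0, z = 0),
                        step_size_nm = c(x = 70, y = 70, z = 50),
                        travel_nm = c(x = 12e6, y = 12e6, z = 4e6),
                        backlash_steps = c(x = 0, y = 0, z = 0),
                        drift_rate_nm_per_hour = c(x = 0, y = 0, z = 0)) {
  step_size_nm <- per_axis(step_size_nm)
  travel_nm <- per_axis(travel_nm)
  backlash_steps <- per_axis(backlash_steps)
  drift_rate_nm_per_hour <- per_axis(drift_rate_nm_per_hour)
  if (any(step_size_nm <= 0)) stop("step sizes must be positive", call. = FALSE)
  if (any(travel_nm <= 0)) stop("travel must be positive", call. = FALSE)
  if (any(backlash_steps < 0)) {
    stop("backlash_steps must be non-negative", call. = FALSE)
  }
  centre_steps <- round(travel_nm / 2 / step_size_nm)
  st <- structure(
    list(
      commanded_steps = centre_steps,
      physical_steps = centre_steps,
      centre_steps = centre_steps,
      step_size_nm = step_size_nm,
      travel_nm = travel_nm,
      backlash_steps = round(backlash_steps),
      last_move_direction = c(x = 0, y = 0, z = 0),
      drift_rate_nm_per_hour = drift_rate_nm_per_hour,
      drift_offset_nm = c(x = 0, y = 0, z = 0),
      clamped = FALSE
    ),
    class = "vs_stage"
  )
  st <- move_to(st, per_axis(position_nm))
  # the stage starts settled at its initial position: no pending slack
  st$physical_steps <- st$commanded_steps
  st$last_move_direction <- c(x = 0, y = 0, z = 0)
  st
}

#' Move the stage to an absolute position
#'
#' The target is quantized to whole steps (round half to even). Targets
#' outside the travel range are clamped to the nearest limit and the
#' stage's `clamped` flag is set. The physical position follows the
#' commanded position through a mechanical-play (backlash) element, so it
#' can lag by up to `backlash_steps` steps after a direction reversal.
#'
#' @param stage a [stage_state()] object.
#' @param target_nm named per-axis vector of absolute positions in nm
#'   (centre-of-travel origin); axes not named are left unchanged.
#' @return the updated `vs_stage`.
#' @export
move_to <- function(stage, target_nm) {
  stopifnot(inherits(stage, "vs_stage"))
  target_nm <- per_axis(target_nm, default = stage_position_nm(stage, "commanded"))
  max_steps <- floor(stage$travel_nm / stage$step_size_nm)
  # nm coordinates are relative to the centre-of-travel step, so targets
  # quantize against a step-aligned origin; round() is round-half-to-even,
  # the documented quantization rule
  steps <- stage$centre_steps + round(target_nm / stage$step_size_nm)
  clamped <- steps < 0 | steps > max_steps
  steps <- pmin(pmax(steps, 0), max_steps)
  delta <- steps - stage$commanded_steps
  moved <- delta != 0
  stage$last_move_direction[moved] <- sign(delta[moved])
  stage$commanded_steps <- steps
  # mechanical play: physical is dragged once the slack is taken up
  b <- stage$backlash_steps
  stage$physical_steps <- pmin(pmax(stage$physical_steps, steps - b), steps)
  stage$clamped <- any(clamped)
  stage
}

#' Accumulate mechanical drift
#'
#' Offsets the physical (not commanded) position by
#' `drift_rate_nm_per_hour * elapsed_hours` per axis. Drift is additive and
#' independent of any moves made between calls.
#'
#' @param stage a [stage_state()] object.
#' @param elapsed_hours non-negative elapsed time in hours.
#' @return the updated `vs_stage`.
#' @export
apply_drift <- function(stage, elapsed_hours) {
  stopifnot(inherits(stage, "vs_stage"))
  if (!is.numeric(elapsed_hours) || length(elapsed_hours) != 1L ||
    is.na(elapsed_hours) || elapsed_hours < 0) {
    stop("elapsed_hours must be a single non-negative number", call. = FALSE)
  }
  stage$drift_offset_nm <- stage$drift_offset_nm +
    stage$drift_rate_nm_per_hour * elapsed_hours
  stage
}

#' Stage position in nm
#'
#' @param stage a [stage_state()] object.
#' @param which `"physical"` (commanded position through backlash, plus
#'   accumulated drift) or `"commanded"` (quantized target).
#' @return named per-axis vector in nm, centre-of-travel origin.
#' @export
stage_position_nm <- function(stage, which = c("physical", "commanded")) {
  stopifnot(inherits(stage, "vs_stage"))
  which <- match.arg(which)
  offset <- stage$centre_steps * stage$step_size_nm
  if (which == "commanded") {
    stage$commanded_steps * stage$step_size_nm - offset
  } else {
    stage$physical_steps * stage$step_size_nm - offset + stage$drift_offset_nm
  }
}

#' @export
print.vs_stage <- function(x, ...) {
  p <- stage_position_nm(x)
  cat("<vs_stage>\n")
  cat(sprintf(
    "  physical  (nm): x=%.0f y=%.0f z=%.0f\n", p["x"], p["y"], p["z"]
  ))
  c <- stage_position_nm(x, "commanded")
  cat(sprintf(
    "  commanded (nm): x=%.0f y=%.0f z=%.0f%s\n", c["x"], c["y"], c["z"],
    if (x$clamped) "  [clamped]" else ""
  ))
  cat(sprintf(
    "  step (nm): x=%g y=%g z=%g; backlash (steps): x=%g y=%g z=%g\n",
    x$step_size_nm["x"], x$step_size_nm["y"], x$step_size_nm["z"],
    x$backlash_steps["x"], x$backlash_steps["y"], x$backlash_steps["z"]
  ))
  invisible(x)
}
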