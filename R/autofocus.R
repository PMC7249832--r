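#' Laplacian sharpness metric
#'
#' Mean squared response of the 3x3 discrete Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over the valid (non-border) pixels. RGB
#' input is converted to luminance first. The metric is zero for a uniform
#' image and decreases monotonically as an image is blurred, which makes it
#' a standard focus measure for brightfield microscopy.
#'
#' @param image numeric matrix (grayscale) or `[h, w, 3]` array, or a
#'   `vs_frame`.
#' @return non-negative sharpness score.
#' @export
laplacian_sharpness <- function(image) {
  if (inherits(image, "vs_frame")) image <- image$pixels
  m <- as_gray(image)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("image must be at least 3x3 for the Laplacian metric", call. = FALSE)
  }
  h <- nrow(m)
  w <- ncol(m)
  core <- m[2:(h - 1), 2:(w - 1)]
  lap <- m[1:(h - 2), 2:(w - 1)] + m[3:h, 2:(w - 1)] +
    m[2:(h - 1), 1:(w - 2)] + m[2:(h - 1), 3:w] - 4 * core
  mean(lap^2)
}

focus_result <- function(best_z_nm, samples, method, at_boundary) {
  structure(
    list(
      best_z_nm = best_z_nm, samples = samples, method = method,
      at_boundary = at_boundary
    ),
    class = "vs_focus"
  )
}

#' @export
print.vs_focus <- function(x, ...) {
  cat(sprintf(
    "<vs_focus> method=%s best_z=%.0f nm (%d samples%s)\n",
    x$method, x$best_z_nm, nrow(x$samples),
    if (x$at_boundary) ", at boundary" else ""
  ))
  invisible(x)
}

## Vertex of the parabola through three (x, y) points around an arg-max.
## Falls back to the middle x when the points are collinear.
parabolic_vertex <- function(x, y) {
  denom <- (y[1L] - 2 * y[2L] + y[3L])
  if (abs(denom) < .Machine$double.eps * max(abs(y), 1)) {
    return(x[2L])
  }
  # assumes uniform spacing; offset in units of the spacing from x[2]
  offset <- 0.5 * (y[1L] - y[3L]) / denom
  x[2L] + offset * (x[3L] - x[1L]) / 2
}

## Move z approaching from below so backlash is always taken up in the
## same direction.
approach_z <- function(mic, z_nm, pre_offset_nm = NULL) {
  if (is.null(pre_offset_nm)) {
    b <- mic$stage$backlash_steps[["z"]] * mic$stage$step_size_nm[["z"]]
    pre_offset_nm <- b + 2 * mic$stage$step_size_nm[["z"]]
  }
  mic_move(mic, c(z = z_nm - pre_offset_nm))
  mic_move(mic, c(z = z_nm))
  invisible(mic)
}

#' Sharpness-sweep autofocus
#'
#' Steps the stage through `n_points` equally spaced z positions, always
#' approached from below (so backlash is taken up in a constant direction),
#' captures a frame at each, and scores it with [laplacian_sharpness()].
#' The peak is refined by fitting a parabola through the three samples
#' around the arg-max, unless the peak lies at either end of the range, in
#' which case the result is flagged `at_boundary` and not refined. The
#' stage is left at the best focus.
#'
#' @param mic a [virtual_microscope()].
#' @param z_range_nm length-2 vector, absolute z range to sweep (nm).
#' @param n_points number of positions (at least 3).
#' @param sharpness_fn focus metric applied to each (binned) frame;
#'   defaults to [laplacian_sharpness()].
#' @param preview_binning integer block-mean binning applied to each frame
#'   before the metric, emulating the downscaled preview stream that focus
#'   metrics run on in camera pipelines; binning averages sensor noise
#'   down and moves the specimen's fine detail towards the Nyquist
#'   frequency, both of which raise the metric's signal-to-noise ratio.
#'   Set to 1 to score full-resolution frames.
#' @return a `vs_focus`: `best_z_nm`, the sampled curve (`samples` with
#'   columns `z_nm`, `score`, `frame_bytes`, `timestamp_s`), `method`, and
#'   `at_boundary`.
#' @export
autofocus_sweep <- function(mic, z_range_nm, n_points = 11L,
                            sharpness_fn = laplacian_sharpness,
                            preview_binning = 4L) {
  stopifnot(inherits(mic, "vs_microscope"), length(z_range_nm) == 2L)
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be at least 3", call. = FALSE)
  zs <- seq(min(z_range_nm), max(z_range_nm), length.out = n_points)

  approach_z(mic, zs[1L])
  samples <- data.frame(
    z_nm = zs, score = NA_real_, frame_bytes = NA_integer_,
    timestamp_s = NA_real_
  )
  for (i in seq_along(zs)) {
    mic_move(mic, c(z = zs[i]))
    fr <- mic_capture(mic)
    preview <- bin_image(as_gray(fr$pixels), preview_binning)
    samples$score[i] <- sharpness_fn(preview)
    samples$frame_bytes[i] <- fr$compressed_size_bytes
    samples$timestamp_s[i] <- fr$timestamp_s
  }

  best_i <- which.max(samples$score) # ties: which.max takes the smallest z
  at_boundary <- best_i == 1L || best_i == n_points
  best_z <- if (at_boundary) {
    zs[best_i]
  } else {
    idx <- (best_i - 1L):(best_i + 1L)
    z_hat <- parabolic_vertex(zs[idx], samples$score[idx])
    min(max(z_hat, zs[1L]), zs[n_points])
  }
  approach_z(mic, best_z)
  focus_result(best_z, samples, "laplacian_sweep", at_boundary)
}

#' Fast autofocus from compressed frame sizes
#'
#' Moves the stage through the z range in a single continuous pass while
#' the camera streams, and uses the byte size of each JPEG-compressed frame
#' as a proxy for sharpness: in-focus frames carry more high-frequency
#' detail and compress less. The size series is smoothed with a centred
#' moving average, the peak frame is mapped back to z through the
#' constant-velocity time-position model, and the stage returns to that z
#' approaching from the standard direction. Because the range is sampled in
#' one pass with no per-position settling, this needs an order of magnitude
#' fewer stage settles than the sharpness sweep.
#'
#' @param mic a [virtual_microscope()].
#' @param z_range_nm length-2 vector, absolute z range to sweep (nm).
#' @param speed_nm_per_s stage speed during the pass.
#' @param smooth_window moving-average window (frames).
#' @param latency_s camera pipeline latency subtracted from frame
#'   timestamps before mapping them to stage position.
#' @param min_rel_variation minimum relative variation
#'   `(max - min) / mean` of the size series; below it the scene is judged
#'   featureless and an error `"no focus found"` is raised.
#' @return a `vs_focus` with `method = "jpeg_fast"`; `samples$score` holds
#'   the smoothed byte sizes.
#' @export
jpeg_fast_autofocus <- function(mic, z_range_nm, speed_nm_per_s = 20000,
                                smooth_window = 3L, latency_s = 0,
                                min_rel_variation = 0.05) {
  stopifnot(
    inherits(mic, "vs_microscope"), length(z_range_nm) == 2L,
    speed_nm_per_s > 0
  )
  z0 <- min(z_range_nm)
  z1 <- max(z_range_nm)
  approach_z(mic, z0)

  dt <- 1 / mic$camera$fps
  t_start <- mic$time_s
  zs <- numeric(0)
  bytes <- numeric(0)
  ts <- numeric(0)
  elapsed <- 0
  repeat {
    z_cmd <- z0 + speed_nm_per_s * elapsed
    if (z_cmd > z1) break
    mic_move(mic, c(z = z_cmd), settle = FALSE)
    fr <- mic_capture(mic) # advances the clock by one frame interval
    zs <- c(zs, z_cmd)
    bytes <- c(bytes, fr$compressed_size_bytes)
    ts <- c(ts, fr$timestamp_s)
    elapsed <- mic$time_s - t_start
  }
  if (length(bytes) < 5L) {
    stop(
      "fewer than 5 frames captured during the focus pass; ",
      "reduce speed_nm_per_s or widen the range",
      call. = FALSE
    )
  }
  if ((max(bytes) - min(bytes)) / mean(bytes) < min_rel_variation) {
    stop("no focus found: compressed frame size is flat over the range",
      call. = FALSE
    )
  }
  smoothed <- moving_average(bytes, smooth_window)
  peak_i <- which.max(smoothed)
  # constant-velocity time -> position model
  z_peak <- z0 + speed_nm_per_s * (ts[peak_i] - ts[1L] - latency_s)
  z_peak <- min(max(z_peak, z0), z1)

  approach_z(mic, z_peak)
  samples <- data.frame(
    z_nm = zs, score = smoothed, frame_bytes = bytes, timestamp_s = ts
  )
  at_boundary <- peak_i == 1L || peak_i == length(bytes)
  focus_result(z_peak, samples, "jpeg_fast", at_boundary)
}
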