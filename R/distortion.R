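## Radial distortion from a scanned straight edge. Because the optics are
## axisymmetric, any distortion must be too: a straight line appears
## straight only through the centre of the field and bows as it is
## translated outward. Detected edge points from several positions across
## the field are fit with the single-coefficient radial model
## r' = r (1 + k r^2), with r normalized to the image half-diagonal.

#' Fit an axisymmetric radial distortion model to straight-edge scans
#'
#' Each element of `edge_positions` holds the detected points of a
#' nominally straight, near-vertical edge at one scan position: a data
#' frame with columns `x_px` and `y_px` (0-based pixel coordinates). The
#' model is that an undistorted point at normalized radius r appears at
#' `r * (1 + k * r^2)` (r = 1 at the half-diagonal). The unknown true
#' line abscissae and k are estimated jointly by alternating least
#' squares on the straight-line residuals.
#'
#' @param edge_positions list (length >= 5) of data frames with `x_px`,
#'   `y_px`.
#' @param sensor_px sensor size `c(width, height)` in pixels, defining the
#'   image centre and the normalization radius.
#' @param max_iter alternating-least-squares iterations.
#' @return an object of class `vs_distortion`: `k`,
#'   `max_fractional_displacement_pct` (worst-case displacement across the
#'   field as % of field width), `line_offsets_px`, `n_points`.
#' @export
estimate_distortion <- function(edge_positions, sensor_px, max_iter = 25L) {
  if (!is.list(edge_positions) || length(edge_positions) < 5L) {
    stop("need detected edges from at least 5 scan positions", call. = FALSE)
  }
  w <- sensor_px[[1L]]
  h <- sensor_px[[2L]]
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  r_norm <- sqrt(cx^2 + cy^2)

  xs <- lapply(edge_positions, function(d) d$x_px - cx)
  ys <- lapply(edge_positions, function(d) (d$y_px - cy))
  n_lines <- length(xs)

  u <- vapply(xs, mean, numeric(1L)) # per-line true offset estimates
  if (all(abs(u) < 0.02 * w)) {
    stop(
      "degenerate geometry: all scanned lines pass through the image ",
      "centre; distortion is unobservable",
      call. = FALSE
    )
  }
  k <- 0
  for (it in seq_len(max_iter)) {
    # pooled linear update of k given the line offsets; centre the
    # regression within each line, because each line's unknown offset
    # absorbs the mean displacement and only the bow along the line
    # (the within-line variation) identifies k
    num <- 0
    den <- 0
    for (i in seq_len(n_lines)) {
      r2 <- (u[i]^2 + ys[[i]]^2) / r_norm^2
      d_c <- (xs[[i]] - u[i]) - mean(xs[[i]] - u[i])
      w_c <- u[i] * r2 - mean(u[i] * r2)
      num <- num + sum(w_c * d_c)
      den <- den + sum(w_c^2)
    }
    k_new <- if (den > 0) num / den else 0
    # per-line offset update given k
    u_new <- vapply(seq_len(n_lines), function(i) {
      r2 <- (u[i]^2 + ys[[i]]^2) / r_norm^2
      mean(xs[[i]] / (1 + k_new * r2))
    }, numeric(1L))
    if (max(abs(u_new - u)) < 1e-9 && abs(k_new - k) < 1e-12) {
      u <- u_new
      k <- k_new
      break
    }
    u <- u_new
    k <- k_new
  }

  structure(
    list(
      k = k,
      max_fractional_displacement_pct = 100 * abs(k) * r_norm / w,
      line_offsets_px = u + cx,
      n_points = sum(vapply(xs, length, integer(1L))),
      sensor_px = c(width = w, height = h)
    ),
    class = "vs_distortion"
  )
}

#' @export
print.vs_distortion <- function(x, ...) {
  cat(sprintf(
    "<vs_distortion> k=%.3e, max displacement %.3f%% of field width (%d points)\n",
    x$k, x$max_fractional_displacement_pct, x$n_points
  ))
  invisible(x)
}

#' Measure distortion by scanning a straight edge across the field
#'
#' Full pipeline: a vertical knife-edge specimen is translated to
#' `n_positions` stage positions so the edge crosses the field of view at
#' evenly spaced columns, the edge is detected in every row of every
#' frame, and the pooled points are fit with [estimate_distortion()].
#'
#' @param optics an [optics_config()]; its `distortion_k` is what the scan
#'   should recover.
#' @param camera a [camera_config()].
#' @param n_positions number of scan positions across the field (>= 5).
#' @param margin_fraction the edge visits columns from `margin_fraction`
#'   to `1 - margin_fraction` of the width.
#' @param seed instrument seed.
#' @return a `vs_distortion` (see [estimate_distortion()]).
#' @export
measure_distortion_scan <- function(optics = optics_preset("0.65NA-dry"),
                                    camera = camera_config(),
                                    n_positions = 9L,
                                    margin_fraction = 0.08,
                                    seed = 1L) {
  stopifnot(n_positions >= 5L)
  w <- camera$sensor_px[["width"]]
  h <- camera$sensor_px[["height"]]
  pitch <- optics$pixel_pitch_nm
  extent_um <- 2 * (max(w, h) * pitch * 1.5) / 1e3 + 100
  spec <- specimen_knife_edge(
    edge_x_um = 0, angle_deg = 0, extent_um = extent_um
  )
  mic <- virtual_microscope(spec,
    optics = optics, camera = camera, seed = seed
  )

  fracs <- seq(margin_fraction, 1 - margin_fraction, length.out = n_positions)
  cx <- (w - 1) / 2
  points <- vector("list", n_positions)
  for (i in seq_len(n_positions)) {
    target_col <- fracs[i] * (w - 1)
    stage_x <- -(target_col - cx) * pitch # edge at sample x = 0
    mic_move(mic, c(x = stage_x))
    fr <- mic_capture(mic)
    cr <- row_edge_crossings(as_gray(fr$pixels))
    ok <- which(!is.na(cr$crossing_px))
    points[[i]] <- data.frame(
      x_px = cr$crossing_px[ok], y_px = ok - 1
    )
  }
  estimate_distortion(points, sensor_px = c(w, h))
}
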