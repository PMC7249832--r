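#' Execute a scan plan on a virtual microscope
#'
#' Visits every site of the plan in order: moves laterally, runs the
#' site's autofocus policy, and captures the z-stack with offsets applied
#' relative to the found focus, always approaching each z from below so
#' backlash is taken up in a constant direction. Time-lapse plans wait for
#' each site's scheduled capture time (stage drift accumulates during the
#' wait). If autofocus fails at a site (error, or peak at the sweep
#' boundary), the site is flagged and its focus is predicted from the
#' previously focused sites by a plane fit - the thin flat-sample
#' assumption that underlies image-based autofocus in the first place.
#'
#' @param plan a `vs_scanplan`.
#' @param mic a [virtual_microscope()].
#' @param af_range_nm z range swept by per-site autofocus, centred on the
#'   current focus estimate.
#' @param af_points sweep points for the Laplacian method.
#' @param af_speed_nm_per_s stage speed for the compressed-size method.
#' @return an object of class `vs_tileset`: `tiles` (each with the frame,
#'   grid index, z offset and focus metadata), a `manifest` data frame
#'   (one row per capture), and the plan.
#' @export
execute_scan <- function(plan, mic, af_range_nm = 20000, af_points = 9L,
                         af_speed_nm_per_s = 20000) {
  stopifnot(inherits(plan, "vs_scanplan"), inherits(mic, "vs_microscope"))
  tiles <- list()
  rows <- list()
  focused <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))

  for (s_idx in seq_along(plan$sites)) {
    site <- plan$sites[[s_idx]]
    if (!is.na(site$capture_time_s) && site$capture_time_s > mic$time_s) {
      mic_advance_time(mic, site$capture_time_s - mic$time_s)
    }
    if (!is.null(site$target_xy_nm)) {
      mic_move(mic, c(
        x = site$target_xy_nm[["x"]], y = site$target_xy_nm[["y"]]
      ))
    }
    z_here <- mic_position(mic, "commanded")[["z"]]

    af_failed <- FALSE
    af_boundary <- FALSE
    focus <- NULL
    if (site$autofocus_policy != "none") {
      rng <- z_here + c(-0.5, 0.5) * af_range_nm
      focus <- tryCatch(
        {
          coarse <- switch(site$autofocus_policy,
            laplacian = autofocus_sweep(mic, rng, n_points = af_points),
            jpeg = jpeg_fast_autofocus(mic, rng,
              speed_nm_per_s = af_speed_nm_per_s
            )
          )
          if (coarse$at_boundary) {
            coarse
          } else {
            # fine pass around the coarse peak: the coarse spacing bounds
            # the coarse error, so +/- 1.5 spacings brackets the focus
            spacing <- if (nrow(coarse$samples) > 1L) {
              mean(diff(coarse$samples$z_nm))
            } else {
              af_range_nm / af_points
            }
            autofocus_sweep(
              mic, coarse$best_z_nm + c(-1.5, 1.5) * spacing,
              n_points = af_points
            )
          }
        },
        error = function(e) NULL
      )
      if (is.null(focus) || focus$at_boundary) {
        af_failed <- TRUE
        af_boundary <- !is.null(focus) && focus$at_boundary
        z_pred <- predict_focus_plane(focused, site$target_xy_nm, z_here)
        approach_z(mic, z_pred)
      }
    }
    focus_z <- mic_position(mic, "commanded")[["z"]]
    if (site$autofocus_policy != "none" && !af_failed) {
      xy <- if (is.null(site$target_xy_nm)) {
        mic_position(mic, "commanded")[c("x", "y")]
      } else {
        site$target_xy_nm
      }
      focused <- rbind(
        focused,
        data.frame(x = xy[["x"]], y = xy[["y"]], z = focus_z)
      )
    }

    offsets <- sort(site$z_offsets_nm)
    approach_z(mic, focus_z + offsets[1L])
    for (off in offsets) {
      mic_move(mic, c(z = focus_z + off))
      fr <- mic_capture(mic)
      tiles[[length(tiles) + 1L]] <- list(
        frame = fr,
        site_index = s_idx,
        grid_index = site$grid_index,
        site_xy_nm = if (is.null(site$target_xy_nm)) {
          fr$commanded_position_nm[c("x", "y")]
        } else {
          site$target_xy_nm
        },
        z_offset_nm = off,
        focus_z_nm = focus_z,
        focus = focus
      )
      rows[[length(rows) + 1L]] <- data.frame(
        site = s_idx,
        i = site$grid_index[["i"]], j = site$grid_index[["j"]],
        x_nm = fr$commanded_position_nm[["x"]],
        y_nm = fr$commanded_position_nm[["y"]],
        z_offset_nm = off,
        z_commanded_nm = fr$commanded_position_nm[["z"]],
        z_true_nm = fr$true_position_nm[["z"]],
        focus_z_nm = focus_z,
        af_method = site$autofocus_policy,
        af_failed = af_failed,
        af_at_boundary = af_boundary,
        frame_bytes = fr$compressed_size_bytes,
        timestamp_s = fr$timestamp_s
      )
    }
  }

  structure(
    list(
      tiles = tiles,
      manifest = do.call(rbind, rows),
      plan = plan,
      pixel_pitch_nm = mic$optics$pixel_pitch_nm
    ),
    class = "vs_tileset"
  )
}

## Predict focus z at a site from previously focused sites: plane fit when
## at least 3 are available, otherwise their mean, otherwise the current z.
predict_focus_plane <- function(focused, xy, fallback_z) {
  if (nrow(focused) >= 3L && !is.null(xy)) {
    X <- cbind(1, focused$x, focused$y)
    fit <- lm.fit(X, focused$z)
    b <- coef(fit)
    b[is.na(b)] <- 0
    b[[1L]] + b[[2L]] * xy[["x"]] + b[[3L]] * xy[["y"]]
  } else if (nrow(focused) >= 1L) {
    mean(focused$z)
  } else {
    fallback_z
  }
}

#' Central tiles of a tile set
#'
#' The 0-offset frame of each z-stack: the ones a mosaic is built from.
#' @param tiles a `vs_tileset`.
#' @return list of tiles.
#' @export
central_tiles <- function(tiles) {
  stopifnot(inherits(tiles, "vs_tileset"))
  Filter(function(t) t$z_offset_nm == 0, tiles$tiles)
}

#' @export
print.vs_tileset <- function(x, ...) {
  cat(sprintf(
    "<vs_tileset> %d captures at %d site(s)%s\n",
    length(x$tiles), length(x$plan$sites),
    if (any(x$manifest$af_failed)) {
      sprintf(" (%d site(s) flagged)", sum(
        tapply(x$manifest$af_failed, x$manifest$site, any)
      ))
    } else {
      ""
    }
  ))
  invisible(x)
}
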