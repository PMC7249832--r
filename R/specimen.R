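#' Virtual specimen field
#'
#' A specimen is a pure function of sample-plane position: a base intensity
#' field (flat background, knife edge, or calibration grid) optionally
#' overlaid with disk primitives (a blood-smear-like cell field). The
#' in-focus z position varies over the slide as the plane
#' `z = a*x + b*y + c` (the focal surface), which models sample tilt.
#'
#' All intensities are relative transmittances in \[0, 1\]. Boundaries are
#' softened over roughly half a pixel at render time so sharpness varies
#' smoothly with defocus.
#'
#' @param primitives list of primitive descriptions; each is a list with a
#'   `type` of `"flat"`, `"edge"`, `"grid"` (base fields, applied first) or
#'   `"disk"` (composited on top). See the convenience constructors
#'   [specimen_flat()], [specimen_knife_edge()], [specimen_grid()] and
#'   [specimen_blood_smear()].
#' @param extent_um lateral size of the virtual slide (square), in microns;
#'   rendering outside it is an error.
#' @param focal_surface named vector `c(a, b, c)`: in-focus z in nm at
#'   sample position (x, y) nm is `a*x + b*y + c`.
#' @param background background intensity used where no primitive applies.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @return an object of class `vs_specimen`.
#' @export
specimen_field <- function(primitives = list(),
                           extent_um = 2000,
                           focal_surface = c(a = 0, b = 0, c = 0),
                           background = 0.85,
                           channels = 1L) {
  stopifnot(extent_um > 0, channels %in% c(1L, 3L))
  fs <- c(a = 0, b = 0, c = 0)
  fs[names(per_axis_focal(focal_surface))] <- per_axis_focal(focal_surface)
  structure(
    list(
      primitives = primitives,
      extent_um = extent_um,
      focal_surface = fs,
      background = background,
      channels = as.integer(channels)
    ),
    class = "vs_specimen"
  )
}

per_axis_focal <- function(v) {
  if (is.null(names(v))) names(v) <- c("a", "b", "c")[seq_along(v)]
  bad <- setdiff(names(v), c("a", "b", "c"))
  if (length(bad) > 0L) {
    stop("focal_surface components must be named a, b, c", call. = FALSE)
  }
  v
}

#' In-focus z of the focal surface at a sample position
#'
#' @param specimen a [specimen_field()] object.
#' @param x_nm,y_nm sample-plane coordinates in nm.
#' @return in-focus z in nm.
#' @export
focal_z_nm <- function(specimen, x_nm, y_nm) {
  fs <- specimen$focal_surface
  fs[["a"]] * x_nm + fs[["b"]] * y_nm + fs[["c"]]
}

#' @rdname specimen_field
#' @param intensity flat-field intensity.
#' @export
specimen_flat <- function(intensity = 0.9, extent_um = 2000,
                          focal_surface = c(a = 0, b = 0, c = 0)) {
  specimen_field(
    list(list(type = "flat", intensity = intensity)),
    extent_um = extent_um, focal_surface = focal_surface,
    background = intensity
  )
}

#' @rdname specimen_field
#' @param edge_x_um x position (microns) where the near-vertical edge
#'   crosses y = 0.
#' @param angle_deg tilt of the edge from vertical, degrees (positive tilts
#'   the top of the edge towards +x).
#' @param lo,hi intensities on the dark (left) and bright (right) sides.
#' @export
specimen_knife_edge <- function(edge_x_um = 0, angle_deg = 1,
                                lo = 0.05, hi = 0.95,
                                extent_um = 2000,
                                focal_surface = c(a = 0, b = 0, c = 0)) {
  specimen_field(
    list(list(
      type = "edge", edge_x_um = edge_x_um, angle_deg = angle_deg,
      lo = lo, hi = hi
    )),
    extent_um = extent_um, focal_surface = focal_surface
  )
}

#' @rdname specimen_field
#' @param pitch_um grid period in microns.
#' @param line_width_um width of the dark grid lines in microns.
#' @export
specimen_grid <- function(pitch_um = 10, line_width_um = 1,
                          lo = 0.1, hi = 0.9, extent_um = 2000,
                          focal_surface = c(a = 0, b = 0, c = 0)) {
  stopifnot(pitch_um > line_width_um)
  specimen_field(
    list(list(
      type = "grid", pitch_um = pitch_um, line_width_um = line_width_um,
      lo = lo, hi = hi
    )),
    extent_um = extent_um, focal_surface = focal_surface
  )
}

#' @rdname specimen_field
#' @param region_um side of the square region (centred on the origin) that
#'   is populated with cells; outside it the slide is bare background.
#' @param density_per_mm2 number of cells per square millimetre inside the
#'   populated region. The default emulates a well-spread thin-smear
#'   monolayer.
#' @param cell_radius_um mean cell radius in microns (red blood cells are
#'   about 7.5 um across).
#' @param seed seed for the reproducible random cell layout.
#' @export
specimen_blood_smear <- function(region_um = 500,
                                 density_per_mm2 = 8000,
                                 cell_radius_um = 3.75,
                                 texture_amplitude = 0.18,
                                 texture_scale_um = 1.2,
                                 extent_um = 2000,
                                 focal_surface = c(a = 0, b = 0, c = 0),
                                 seed = 1) {
  n <- max(1L, round(density_per_mm2 * (region_um / 1000)^2))
  sm <- with_seed(seed, {
    cx <- runif(n, -region_um / 2, region_um / 2)
    cy <- runif(n, -region_um / 2, region_um / 2)
    r <- cell_radius_um * exp(rnorm(n, 0, 0.08))
    int <- pmin(pmax(rnorm(n, 0.40, 0.05), 0.15), 0.6)
    # stain granularity: a fixed, band-limited random field (sum of
    # random plane waves) carried by the cells, the sub-micron detail a
    # focus metric locks onto
    m_comp <- 32L
    k_mag <- 2 * pi / (texture_scale_um * 1e3) * runif(m_comp, 0.7, 1.3)
    k_ang <- runif(m_comp, 0, 2 * pi)
    list(
      cx = cx, cy = cy, r = r, int = int,
      texture = list(
        amplitude = texture_amplitude,
        kx = k_mag * cos(k_ang), ky = k_mag * sin(k_ang),
        phase = runif(m_comp, 0, 2 * pi)
      )
    )
  })
  prim <- lapply(seq_len(n), function(i) {
    list(
      type = "disk", centre_um = c(sm$cx[i], sm$cy[i]), radius_um = sm$r[i],
      intensity = sm$int[i], central_pallor = 0.2
    )
  })
  sp <- specimen_field(
    prim,
    extent_um = extent_um, focal_surface = focal_surface, background = 0.88
  )
  sp$texture <- sm$texture
  sp
}

## Band-limited texture field: unit-ish variance sum of random cosines.
texture_eval <- function(tex, x_nm, y_nm) {
  m <- length(tex$kx)
  ph <- outer(as.vector(x_nm), tex$kx) + outer(as.vector(y_nm), tex$ky)
  ph <- sweep(ph, 2L, tex$phase, "+")
  v <- rowSums(cos(ph)) * sqrt(2 / m) * tex$amplitude
  matrix(v, nrow(x_nm), ncol(x_nm))
}

## Soft step from 0 to 1 over width `soft` centred on d = 0.
smoothstep01 <- function(d, soft) {
  t <- pmin(pmax(d / soft + 0.5, 0), 1)
  t * t * (3 - 2 * t)
}

#' Evaluate the specimen's ideal intensity at sample-plane coordinates
#'
#' Vectorized over matrices of coordinates; used by the renderer. Exposed
#' so ground-truth rasters can be built in tests.
#'
#' @param specimen a [specimen_field()] object.
#' @param x_nm,y_nm numeric matrices of sample coordinates in nm.
#' @param soft_nm softening width for primitive boundaries (typically one
#'   pixel pitch).
#' @return matrix (grayscale) or `[h, w, 3]` array of intensities in
#'   \[0, 1\].
#' @export
specimen_intensity <- function(specimen, x_nm, y_nm, soft_nm = 50) {
  stopifnot(inherits(specimen, "vs_specimen"))
  base <- matrix(specimen$background, nrow(x_nm), ncol(x_nm))
  chans <- specimen$channels
  out <- if (chans == 1L) base else rep(list(base), 3L)

  set_field <- function(v) {
    if (chans == 1L) out <<- v else out <<- rep(list(v), 3L)
  }
  # blend a local patch (rows i, cols j) against coverage alpha
  blend <- function(i, j, alpha, value, colour = NULL) {
    if (chans == 1L) {
      out[i, j] <<- out[i, j] * (1 - alpha) + value * alpha
    } else {
      for (k in 1:3) {
        ch_val <- if (is.null(colour)) value else colour[k]
        out[[k]][i, j] <<- out[[k]][i, j] * (1 - alpha) + ch_val * alpha
      }
    }
  }

  # per-column x range and per-row y range, for disk bounding boxes
  col_x_min <- apply(x_nm, 2L, min); col_x_max <- apply(x_nm, 2L, max)
  row_y_min <- apply(y_nm, 1L, min); row_y_max <- apply(y_nm, 1L, max)

  for (p in specimen$primitives) {
    switch(p$type,
      flat = set_field(matrix(p$intensity, nrow(x_nm), ncol(x_nm))),
      edge = {
        slope <- tan(p$angle_deg * pi / 180)
        d <- x_nm - p$edge_x_um * 1e3 - slope * y_nm
        set_field(p$lo + (p$hi - p$lo) * smoothstep01(d, soft_nm))
      },
      grid = {
        pitch <- p$pitch_um * 1e3
        halfw <- p$line_width_um * 1e3 / 2
        dx <- abs((x_nm %% pitch) - pitch / 2)
        dy <- abs((y_nm %% pitch) - pitch / 2)
        # distance from the nearest line centre (lines at multiples of pitch)
        dline <- pmin(pitch / 2 - dx, pitch / 2 - dy)
        on_line <- 1 - smoothstep01(dline - halfw, soft_nm)
        set_field(p$hi + (p$lo - p$hi) * on_line)
      },
      disk = {
        cx <- p$centre_um[1L] * 1e3
        cy <- p$centre_um[2L] * 1e3
        rad <- p$radius_um * 1e3 + soft_nm
        j <- which(col_x_max >= cx - rad & col_x_min <= cx + rad)
        i <- which(row_y_max >= cy - rad & row_y_min <= cy + rad)
        if (length(i) > 0L && length(j) > 0L) {
          xp <- x_nm[i, j, drop = FALSE]
          yp <- y_nm[i, j, drop = FALSE]
          r <- sqrt((xp - cx)^2 + (yp - cy)^2)
          alpha <- 1 - smoothstep01(r - p$radius_um * 1e3, soft_nm)
          val <- p$intensity
          if (!is.null(p$central_pallor) && p$central_pallor != 0) {
            # brighter biconcave centre, as in red blood cells
            val <- val + p$central_pallor *
              exp(-(r / (0.45 * p$radius_um * 1e3))^2)
          }
          if (!is.null(specimen$texture)) {
            val <- val + texture_eval(specimen$texture, xp, yp)
          }
          blend(i, j, alpha, val, p$colour)
        }
      },
      stop("unknown primitive type: ", p$type, call. = FALSE)
    )
  }
  if (chans == 1L) out else array(unlist(out), c(dim(x_nm), 3L))
}
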