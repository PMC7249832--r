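## Lens-shading (vignetting) calibration: build a coarse per-channel gain
## grid from a flat-field image and apply it by bilinear interpolation,
## emulating the coarse gain table of a hardware image pipeline.

#' Build a lens-shading gain table from a flat-field image
#'
#' The image of a featureless bright target is reduced to a coarse grid of
#' cell means per channel; gains are the ratio of the brightest cell to
#' each cell, so the minimum gain is exactly 1 and corners of a vignetted
#' image receive gains above 1.
#'
#' @param flat_field a `vs_frame` or raster of a uniform bright target,
#'   not saturated.
#' @param grid_dims `c(n_cols, n_rows)` of the gain grid.
#' @param floor_fraction cells darker than this fraction of the brightest
#'   cell abort the calibration (insufficient or uneven illumination).
#' @return an object of class `vs_shading`: `gains` (array
#'   `[n_rows, n_cols, channels]`), `grid_dims`, `sensor_px`.
#' @export
build_shading_table <- function(flat_field, grid_dims = c(32, 24),
                                floor_fraction = 0.05) {
  if (inherits(flat_field, "vs_frame")) flat_field <- flat_field$pixels
  chans <- if (is.matrix(flat_field)) 1L else dim(flat_field)[3L]
  h <- dim(flat_field)[1L]
  w <- dim(flat_field)[2L]
  nc <- as.integer(grid_dims[[1L]])
  nr <- as.integer(grid_dims[[2L]])
  stopifnot(nc >= 2L, nr >= 2L, w >= nc, h >= nr)

  row_cell <- pmin(floor(((seq_len(h) - 0.5) / h) * nr) + 1L, nr)
  col_cell <- pmin(floor(((seq_len(w) - 0.5) / w) * nc) + 1L, nc)

  cell_means <- function(m) {
    sums <- tapply(
      as.vector(m),
      list(row_cell[row(m)], col_cell[col(m)]),
      mean
    )
    matrix(as.numeric(sums), nr, nc)
  }
  gains <- array(NA_real_, c(nr, nc, chans))
  for (ch in seq_len(chans)) {
    m <- if (chans == 1L) flat_field else flat_field[, , ch]
    cm <- cell_means(m)
    if (any(cm < floor_fraction * max(cm))) {
      stop(
        "insufficient illumination: a grid cell mean falls below ",
        floor_fraction * 100, "% of the brightest cell",
        call. = FALSE
      )
    }
    gains[, , ch] <- max(cm) / cm
  }
  structure(
    list(
      gains = gains, grid_dims = c(n_cols = nc, n_rows = nr),
      sensor_px = c(width = w, height = h)
    ),
    class = "vs_shading"
  )
}

## Bilinearly interpolate a cell grid (values at cell centres) to a full
## h x w raster, clamping beyond the outermost cell centres.
interp_cell_grid <- function(cells, h, w) {
  nr <- nrow(cells)
  nc <- ncol(cells)
  # cell-centre coordinates in pixel units (1-based pixel centres)
  yc <- (seq_len(nr) - 0.5) * h / nr + 0.5
  xc <- (seq_len(nc) - 0.5) * w / nc + 0.5
  yq <- pmin(pmax(seq_len(h), yc[1L]), yc[nr])
  xq <- pmin(pmax(seq_len(w), xc[1L]), xc[nc])
  iy <- pmin(findInterval(yq, yc), nr - 1L)
  ix <- pmin(findInterval(xq, xc), nc - 1L)
  ty <- (yq - yc[iy]) / (yc[iy + 1L] - yc[iy])
  tx <- (xq - xc[ix]) / (xc[ix + 1L] - xc[ix])
  # outer products assemble the four corner contributions
  a <- cells[cbind(rep(iy, times = w), rep(ix, each = h))]
  b <- cells[cbind(rep(iy, times = w), rep(ix + 1L, each = h))]
  c_ <- cells[cbind(rep(iy + 1L, times = w), rep(ix, each = h))]
  d <- cells[cbind(rep(iy + 1L, times = w), rep(ix + 1L, each = h))]
  TY <- matrix(rep(ty, times = w), h, w)
  TX <- matrix(rep(tx, each = h), h, w)
  A <- matrix(a, h, w)
  B <- matrix(b, h, w)
  C <- matrix(c_, h, w)
  D <- matrix(d, h, w)
  (1 - TY) * (1 - TX) * A + (1 - TY) * TX * B + TY * (1 - TX) * C + TY * TX * D
}

#' Apply a lens-shading correction
#'
#' Multiplies each pixel by the bilinearly interpolated gain for its
#' position (per channel). Values are clipped to the 8-bit maximum; the
#' number of clipped pixels is reported via the `"n_saturated"` attribute.
#'
#' @param image a `vs_frame` or raster.
#' @param table a `vs_shading` from [build_shading_table()].
#' @return corrected raster with attribute `n_saturated`.
#' @export
apply_shading_correction <- function(image, table) {
  stopifnot(inherits(table, "vs_shading"))
  if (inherits(image, "vs_frame")) image <- image$pixels
  chans <- if (is.matrix(image)) 1L else dim(image)[3L]
  h <- dim(image)[1L]
  w <- dim(image)[2L]
  tab_ch <- dim(table$gains)[3L]
  if (chans != tab_ch && tab_ch != 1L) {
    stop("shading table has ", tab_ch, " channel(s) but image has ", chans,
      call. = FALSE
    )
  }
  out <- image
  n_sat <- 0L
  for (ch in seq_len(chans)) {
    g <- interp_cell_grid(table$gains[, , min(ch, tab_ch)], h, w)
    m <- if (chans == 1L) image else image[, , ch]
    corrected <- m * g
    n_sat <- n_sat + sum(corrected > 255)
    corrected <- pmin(corrected, 255)
    if (chans == 1L) out <- corrected else out[, , ch] <- corrected
  }
  attr(out, "n_saturated") <- n_sat
  out
}

#' Low-frequency flatness of an image
#'
#' Relative RMS deviation of coarse cell means about the global mean:
#' the figure of merit for a shading correction, insensitive to
#' pixel-level sensor noise (which the gain table neither models nor
#' corrects).
#'
#' @param image raster or `vs_frame` (luminance is used for RGB).
#' @param grid_dims `c(n_cols, n_rows)` of the averaging grid.
#' @return relative RMS (e.g. 0.01 for 1%).
#' @export
flatness_rms <- function(image, grid_dims = c(32, 24)) {
  if (inherits(image, "vs_frame")) image <- image$pixels
  m <- as_gray(image)
  h <- nrow(m)
  w <- ncol(m)
  nc <- as.integer(grid_dims[[1L]])
  nr <- as.integer(grid_dims[[2L]])
  row_cell <- pmin(floor(((seq_len(h) - 0.5) / h) * nr) + 1L, nr)
  col_cell <- pmin(floor(((seq_len(w) - 0.5) / w) * nc) + 1L, nc)
  cm <- tapply(as.vector(m), list(row_cell[row(m)], col_cell[col(m)]), mean)
  sqrt(mean((cm - mean(cm))^2)) / mean(cm)
}
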