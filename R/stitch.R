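## Mosaic stitching: pairwise translational registration of adjacent tiles
## by phase correlation on their overlap regions, global positions by
## least squares over the pairwise-offset graph, and compositing of the
## central crop of each tile (tile edges carry the worst optics, so they
## are used only for alignment, never for the final image).

#' Translational offset between two rasters by phase correlation
#'
#' Returns the integer shift `(dy, dx)` such that `b` is approximately `a`
#' shifted by that amount (`b[y, x] == a[y - dy, x - dx]`), and the height
#' of the correlation peak (1 for identical images).
#'
#' @param a,b numeric matrices of equal size.
#' @return list with `shift` (`c(dy, dx)`) and `peak`.
#' @export
phase_correlate <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  h <- nrow(a)
  w <- ncol(a)
  # mean removal and a Hann window suppress edge artefacts
  win <- outer(
    0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1)),
    0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  )
  fa <- fft((a - mean(a)) * win)
  fb <- fft((b - mean(b)) * win)
  r <- fb * Conj(fa)
  r <- r / pmax(Mod(r), 1e-12)
  corr <- Re(fft(r, inverse = TRUE)) / (h * w)
  pk <- which.max(corr)
  py <- (pk - 1L) %% h
  px <- (pk - 1L) %/% h
  if (py > h / 2) py <- py - h
  if (px > w / 2) px <- px - w
  list(shift = c(dy = py, dx = px), peak = max(corr))
}

#' Stitch a tile set into a mosaic
#'
#' Registers adjacent tiles (grid neighbours) by phase correlation of
#' their nominal overlap regions, solves for global tile positions by
#' least squares over the pairwise-offset graph anchored at the first
#' tile, and composites the central crop of each tile at its solved
#' position. Pairs whose correlation peak falls below `corr_threshold`
#' fall back to their nominal offset and are reported in `flagged_pairs`.
#'
#' @param tiles a `vs_tileset` from [execute_scan()] (the 0-offset frame
#'   of each stack is used).
#' @param crop_margin_fraction fraction of each tile's width/height
#'   discarded per side before compositing.
#' @param corr_threshold minimum phase-correlation peak for a pairwise
#'   offset to be trusted.
#' @return an object of class `vs_mosaic`: `image`,
#'   `recovered_offsets_px` (data frame of solved tile origins),
#'   `flagged_pairs`, `crop_margin_fraction`.
#' @export
stitch_tiles <- function(tiles, crop_margin_fraction = 0.25,
                         corr_threshold = 0.1) {
  stopifnot(inherits(tiles, "vs_tileset"))
  stopifnot(crop_margin_fraction >= 0, crop_margin_fraction < 0.5)
  cen <- central_tiles(tiles)
  n <- length(cen)
  if (n == 0L) stop("tile set has no central (0-offset) tiles", call. = FALSE)
  pitch <- tiles$pixel_pitch_nm
  img1 <- as_gray(cen[[1L]]$frame$pixels)
  h <- nrow(img1)
  w <- ncol(img1)

  if (tiles$plan$overlap_fraction < 2 * crop_margin_fraction && n > 1L) {
    stop(sprintf(
      paste0(
        "tile overlap (%.2f) must be at least twice the crop margin ",
        "(%.2f) so that central crops meet"
      ),
      tiles$plan$overlap_fraction, crop_margin_fraction
    ), call. = FALSE)
  }

  # nominal tile origins (row, col) in mosaic pixels from commanded stage
  # positions; y is up in stage coordinates, row is down in the image
  sx <- vapply(cen, function(t) t$site_xy_nm[["x"]], numeric(1L))
  sy <- vapply(cen, function(t) t$site_xy_nm[["y"]], numeric(1L))
  nom_col <- (sx - min(sx)) / pitch
  nom_row <- (max(sy) - sy) / pitch
  gi <- vapply(cen, function(t) t$grid_index[["i"]], numeric(1L))
  gj <- vapply(cen, function(t) t$grid_index[["j"]], numeric(1L))

  # adjacent pairs share a grid edge
  pairs <- list()
  for (aa in seq_len(n)) {
    for (bb in seq_len(n)) {
      if (bb > aa && abs(gi[aa] - gi[bb]) + abs(gj[aa] - gj[bb]) == 1) {
        pairs[[length(pairs) + 1L]] <- c(aa, bb)
      }
    }
  }

  flagged <- data.frame(a = integer(0), b = integer(0), peak = numeric(0))
  d_rows <- numeric(0)
  d_cols <- numeric(0)
  pair_a <- integer(0)
  pair_b <- integer(0)
  for (p in pairs) {
    aa <- p[1L]
    bb <- p[2L]
    nd_row <- round(nom_row[bb] - nom_row[aa])
    nd_col <- round(nom_col[bb] - nom_col[aa])
    # overlap of tile a's pixel box [0,h)x[0,w) with tile b's shifted box
    r0 <- max(0L, nd_row)
    r1 <- min(h, h + nd_row)
    c0 <- max(0L, nd_col)
    c1 <- min(w, w + nd_col)
    res <- c(dy = 0, dx = 0)
    peak <- NA_real_
    if (r1 - r0 >= 8L && c1 - c0 >= 8L) {
      sub_a <- as_gray(cen[[aa]]$frame$pixels)[(r0 + 1L):r1, (c0 + 1L):c1]
      sub_b <- as_gray(cen[[bb]]$frame$pixels)[
        (r0 - nd_row + 1L):(r1 - nd_row), (c0 - nd_col + 1L):(c1 - nd_col)
      ]
      pc <- phase_correlate(sub_a, sub_b)
      peak <- pc$peak
      if (peak >= corr_threshold) {
        # b's content appears shifted by `shift` relative to a, so b's
        # origin moves by the opposite amount
        res <- -pc$shift
      } else {
        flagged <- rbind(flagged, data.frame(a = aa, b = bb, peak = peak))
      }
    } else {
      flagged <- rbind(flagged, data.frame(a = aa, b = bb, peak = NA_real_))
    }
    pair_a <- c(pair_a, aa)
    pair_b <- c(pair_b, bb)
    d_rows <- c(d_rows, nd_row + res[["dy"]])
    d_cols <- c(d_cols, nd_col + res[["dx"]])
  }

  solve_axis <- function(d, nominal) {
    if (n == 1L || length(d) == 0L) {
      return(nominal)
    }
    m <- length(d)
    X <- matrix(0, m + 1L, n)
    y <- numeric(m + 1L)
    for (q in seq_len(m)) {
      X[q, pair_a[q]] <- -1
      X[q, pair_b[q]] <- 1
      y[q] <- d[q]
    }
    X[m + 1L, 1L] <- 1 # anchor the first tile at its nominal origin
    y[m + 1L] <- nominal[1L]
    fit <- lm.fit(X, y)
    b <- coef(fit)
    b[is.na(b)] <- nominal[is.na(b)]
    b
  }
  pos_row <- round(solve_axis(d_rows, nom_row))
  pos_col <- round(solve_axis(d_cols, nom_col))

  # composite central crops
  mr <- round(crop_margin_fraction * h)
  mc <- round(crop_margin_fraction * w)
  ch <- h - 2L * mr
  cw <- w - 2L * mc
  crop_row <- pos_row + mr
  crop_col <- pos_col + mc
  out_r0 <- min(crop_row)
  out_c0 <- min(crop_col)
  H <- max(crop_row) - out_r0 + ch
  W <- max(crop_col) - out_c0 + cw
  canvas <- matrix(0, H, W)
  for (t in seq_len(n)) {
    m <- as_gray(cen[[t]]$frame$pixels)[(mr + 1L):(h - mr), (mc + 1L):(w - mc)]
    rr <- (crop_row[t] - out_r0 + 1L):(crop_row[t] - out_r0 + ch)
    cc <- (crop_col[t] - out_c0 + 1L):(crop_col[t] - out_c0 + cw)
    canvas[rr, cc] <- m
  }

  structure(
    list(
      image = canvas,
      recovered_offsets_px = data.frame(
        i = gi, j = gj, row_px = pos_row, col_px = pos_col,
        nominal_row_px = nom_row, nominal_col_px = nom_col
      ),
      flagged_pairs = flagged,
      crop_margin_fraction = crop_margin_fraction
    ),
    class = "vs_mosaic"
  )
}

#' @export
print.vs_mosaic <- function(x, ...) {
  cat(sprintf(
    "<vs_mosaic> %d x %d px from %d tile(s), %d flagged pair(s)\n",
    nrow(x$image), ncol(x$image), nrow(x$recovered_offsets_px),
    nrow(x$flagged_pairs)
  ))
  invisible(x)
}
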