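## Knife-edge (edge-spread-function) estimation of the point spread
## function. A near-vertical black/white edge is located in every row at
## its 50% crossing; rows are shifted to a common origin and pooled, which
## yields sub-pixel sampling when the edge is slightly tilted; the pooled
## samples are fit with a smoothing spline; taking the square root converts
## intensity to amplitude (coherent imaging), and differentiating gives the
## amplitude PSF, whose FWHM is the resolution figure.

## Per-row 50% crossings of a near-vertical edge, robust to vignetting via
## per-row plateau normalization. Returns a list with `crossing_px`
## (0-based continuous column, NA where no clean crossing), `lo`, `hi`
## (plateau levels) and `ascending` (global polarity).
row_edge_crossings <- function(m, plateau_gap_px = 8L, plateau_width_px = 22L,
                               max_spread_px = 5) {
  h <- nrow(m)
  w <- ncol(m)
  # coarse edge location from the column gradient of the mean row
  col_mean <- colMeans(m)
  x_coarse <- which.max(abs(diff(col_mean)))
  ascending <- diff(col_mean)[x_coarse] > 0

  res <- vapply(seq_len(h), function(r) {
    v <- m[r, ]
    lo_idx <- max(1L, x_coarse - plateau_gap_px - plateau_width_px):
      max(1L, x_coarse - plateau_gap_px)
    hi_idx <- min(w, x_coarse + plateau_gap_px):
      min(w, x_coarse + plateau_gap_px + plateau_width_px)
    left <- mean(v[lo_idx])
    right <- mean(v[hi_idx])
    if (length(lo_idx) < 5L || length(hi_idx) < 5L ||
      abs(right - left) < 1e-9) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    mid <- (left + right) / 2
    if (!ascending) v <- (left + right) - v # flip so the edge rises
    i <- seq_len(w - 1L)
    cross <- which(v[i] < mid & v[i + 1L] >= mid)
    cross <- cross[abs(cross - x_coarse) <= 3 * max_spread_px + 2]
    if (length(cross) == 0L ||
      max(cross) - min(cross) > max_spread_px) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    # sub-pixel location from the centroid of the intensity derivative
    # around the crossing; unlike linear interpolation of the 50% level,
    # the centroid varies smoothly with the true edge position on
    # quantized 8-bit data
    ctr <- round(mean(cross))
    win <- max(1L, ctr - 8L):min(w - 1L, ctr + 8L)
    g <- pmax(v[win + 1L] - v[win], 0)
    g[g < 0.05 * max(g)] <- 0 # suppress plateau noise
    if (sum(g) <= 0) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    x_centroid <- sum((win + 0.5) * g) / sum(g)
    lo <- min(left, right)
    hi <- max(left, right)
    c(x_centroid - 1, lo, hi) # 0-based
  }, numeric(3L))

  list(
    crossing_px = res[1L, ], lo = res[2L, ], hi = res[3L, ],
    ascending = ascending
  )
}

#' Extract a pooled sub-pixel edge-spread profile
#'
#' Locates a dominant near-vertical intensity edge in every row at its 50%
#' crossing, shifts each row so the crossings coincide, pools the samples
#' from all rows (a slightly tilted edge then samples the profile at
#' sub-pixel spacing), and fits the pooled points with a smoothing spline.
#' The smoothing parameter is chosen by generalized cross-validation unless
#' `spar` is given. The result is normalized so the profile runs from 0 to
#' 1, left to right.
#'
#' @param image a `vs_frame`, grayscale matrix or RGB array containing one
#'   dominant near-vertical edge.
#' @param pitch_nm sample-plane pixel pitch in nm (taken from the frame if
#'   `image` is a `vs_frame`).
#' @param window_px half-width, in pixels, of the band around the edge that
#'   enters the fit.
#' @param spar optional smoothing parameter for [stats::smooth.spline()].
#' @param grid_step_nm output sample spacing (default `pitch_nm / 8`).
#' @return an object of class `vs_esf`: `positions_nm` (strictly
#'   increasing), `values` (normalized intensity), `smoothing_parameter`,
#'   `n_rows` (rows used), `n_samples` (pooled points).
#' @export
extract_edge_profile <- function(image, pitch_nm = NULL, window_px = 30L,
                                 spar = NULL, grid_step_nm = NULL) {
  if (inherits(image, "vs_frame")) {
    if (is.null(pitch_nm)) pitch_nm <- image$meta$pixel_pitch_nm
    image <- image$pixels
  }
  if (is.null(pitch_nm)) {
    stop("pitch_nm is required when `image` is a raw raster", call. = FALSE)
  }
  m <- as_gray(image)
  h <- nrow(m)
  w <- ncol(m)
  cr <- row_edge_crossings(m)
  ok <- !is.na(cr$crossing_px)
  if (mean(!ok) > 0.2) {
    stop(sprintf(
      "edge not detected: no clean 50%% crossing in %d of %d rows",
      sum(!ok), h
    ), call. = FALSE)
  }

  xs <- vector("list", sum(ok))
  vs <- vector("list", sum(ok))
  rows <- which(ok)
  for (idx in seq_along(rows)) {
    r <- rows[idx]
    x0 <- cr$crossing_px[r] # 0-based
    j <- max(1L, ceiling(x0 + 1 - window_px)):min(w, floor(x0 + 1 + window_px))
    vals <- (m[r, j] - cr$lo[r]) / (cr$hi[r] - cr$lo[r])
    pos <- ((j - 1) - x0) * pitch_nm
    if (!cr$ascending) {
      pos <- -pos
    }
    xs[[idx]] <- pos
    vs[[idx]] <- vals
  }
  x_pool <- unlist(xs)
  v_pool <- unlist(vs)

  # average the pooled samples in quarter-pixel bins before the spline
  # fit: each bin pools samples from many rows, so sensor noise averages
  # out and the spline's cross-validated smoothing is chosen against the
  # profile shape, not the per-pixel noise
  bin_w <- pitch_nm / 4
  bin_id <- round(x_pool / bin_w)
  bx <- tapply(x_pool, bin_id, mean)
  bv <- tapply(v_pool, bin_id, mean)
  bn <- tapply(v_pool, bin_id, length)
  fit <- if (is.null(spar)) {
    smooth.spline(bx, bv, w = bn)
  } else {
    smooth.spline(bx, bv, w = bn, spar = spar)
  }
  if (is.null(grid_step_nm)) grid_step_nm <- pitch_nm / 8
  half <- (window_px - 1) * pitch_nm
  grid <- seq(-half, half, by = grid_step_nm)
  est <- predict(fit, grid)$y

  # renormalize on the fitted plateaus
  lo_fit <- mean(est[grid < -0.6 * half])
  hi_fit <- mean(est[grid > 0.6 * half])
  values <- (est - lo_fit) / (hi_fit - lo_fit)

  # absolute (unnormalized) plateau intensities, needed to undo the
  # normalization before the intensity -> amplitude square root
  lo_abs <- median(cr$lo[ok]) + lo_fit * (median(cr$hi[ok]) - median(cr$lo[ok]))
  hi_abs <- median(cr$lo[ok]) + hi_fit * (median(cr$hi[ok]) - median(cr$lo[ok]))

  structure(
    list(
      positions_nm = grid, values = values,
      plateau_ratio = max(lo_abs, 0) / hi_abs,
      smoothing_parameter = fit$spar, n_rows = length(rows),
      n_samples = length(x_pool)
    ),
    class = "vs_esf"
  )
}

#' Point spread function from an edge-spread profile
#'
#' Converts the edge response to amplitude by taking its square root
#' (coherent image formation; disable with `sqrt_first = FALSE` for
#' incoherent experiments), differentiates it to obtain the line/point
#' spread profile, normalizes the peak to 1, and measures the full width at
#' half maximum by linear interpolation of the half-maximum crossings
#' (ties resolved towards the widest bracket).
#'
#' @param profile a `vs_esf` from [extract_edge_profile()].
#' @param sqrt_first take the square root of the intensity profile before
#'   differentiating.
#' @return an object of class `vs_psf`: `positions_nm`, `values`
#'   (non-negative, peak 1), `fwhm_nm`.
#' @export
psf_from_edge <- function(profile, sqrt_first = TRUE) {
  stopifnot(inherits(profile, "vs_esf"))
  a <- if (sqrt_first) {
    # undo the [0,1] normalization before the square root: the amplitude
    # profile is sqrt of the *absolute* intensity, and the dark plateau of
    # a real edge is not perfectly black
    ratio <- profile$plateau_ratio %||% 0
    sqrt(pmax(ratio + profile$values * (1 - ratio), 0))
  } else {
    profile$values
  }
  pos <- profile$positions_nm
  d <- diff(a) / diff(pos)
  mid <- (pos[-1L] + pos[-length(pos)]) / 2
  d <- pmax(d, 0)
  pk <- max(d)
  if (pk <= 0) stop("degenerate profile: derivative is non-positive",
    call. = FALSE
  )
  psf <- d / pk
  p <- which.max(psf)

  i <- seq_len(length(psf) - 1L)
  up <- which(psf[i] < 0.5 & psf[i + 1L] >= 0.5 & i < p)
  down <- which(psf[i] >= 0.5 & psf[i + 1L] < 0.5 & i >= p)
  if (length(up) == 0L || length(down) == 0L) {
    stop("profile too short: half-maximum not bracketed on both sides",
      call. = FALSE
    )
  }
  iL <- min(up) # widest bracket
  iR <- max(down)
  xL <- mid[iL] + (0.5 - psf[iL]) / (psf[iL + 1L] - psf[iL]) *
    (mid[iL + 1L] - mid[iL])
  xR <- mid[iR] + (0.5 - psf[iR]) / (psf[iR + 1L] - psf[iR]) *
    (mid[iR + 1L] - mid[iR])

  structure(
    list(positions_nm = mid, values = psf, fwhm_nm = xR - xL),
    class = "vs_psf"
  )
}

#' @export
print.vs_esf <- function(x, ...) {
  cat(sprintf(
    "<vs_esf> %d points over [%.0f, %.0f] nm (%d rows pooled, spar=%.3f)\n",
    length(x$positions_nm), min(x$positions_nm), max(x$positions_nm),
    x$n_rows, x$smoothing_parameter
  ))
  invisible(x)
}

#' @export
print.vs_psf <- function(x, ...) {
  cat(sprintf("<vs_psf> FWHM %.1f nm\n", x$fwhm_nm))
  invisible(x)
}
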