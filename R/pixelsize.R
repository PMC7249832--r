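#' Check sampling density against optical resolution
#'
#' With a Bayer colour filter a 2x2 block of pixels forms one full-colour
#' sampling unit, so the effective sampling pitch is twice the pixel pitch;
#' the image is adequately sampled when this effective pitch is smaller
#' than the optical resolution (PSF FWHM).
#'
#' @param pitch_nm sample-plane distance per pixel, nm.
#' @param resolution_fwhm_nm optical resolution (PSF FWHM), nm.
#' @param bayer_enabled whether a Bayer mosaic halves the per-channel
#'   sampling density.
#' @return list with `effective_pitch_nm`, `resolution_fwhm_nm`,
#'   `adequately_sampled` (logical) and a human-readable `verdict`.
#' @export
#' @examples
#' sampling_check(100, 480, bayer_enabled = TRUE) # 200 nm block < 480 nm
sampling_check <- function(pitch_nm, resolution_fwhm_nm, bayer_enabled) {
  stopifnot(pitch_nm > 0, resolution_fwhm_nm > 0)
  eff <- if (isTRUE(bayer_enabled)) 2 * pitch_nm else pitch_nm
  ok <- eff < resolution_fwhm_nm
  list(
    effective_pitch_nm = eff,
    resolution_fwhm_nm = resolution_fwhm_nm,
    adequately_sampled = ok,
    verdict = if (ok) "adequately sampled" else "undersampled"
  )
}

#' Calibrate pixel size from a periodic grid target
#'
#' Measures the dominant spatial period of a periodic target (e.g. a
#' calibration grid of known pitch) from the averaged row autocorrelation,
#' refines the peak to sub-pixel precision with a parabolic fit, and
#' converts the known physical pitch to a distance-per-pixel and field of
#' view.
#'
#' @param image a `vs_frame` or raster of a periodic grid target.
#' @param known_pitch_um physical period of the target, microns.
#' @param min_period_px smallest period considered, px.
#' @return an object of class `vs_pixcal`: `nm_per_px`, `fov_um`
#'   (`c(width, height)`), `period_px`.
#' @export
calibrate_pixel_size <- function(image, known_pitch_um, min_period_px = 8L) {
  if (inherits(image, "vs_frame")) image <- image$pixels
  m <- as_gray(image)
  h <- nrow(m)
  w <- ncol(m)
  stopifnot(known_pitch_um > 0, w >= 4L * min_period_px)

  # mean row autocorrelation via FFT, unbiased by the row means
  m0 <- m - rowMeans(m)
  n_fft <- 2L * w
  spec <- apply(m0, 1L, function(v) Mod(fft(c(v, numeric(w))))^2)
  ac <- Re(fft(rowMeans(spec), inverse = TRUE)) / n_fft
  ac <- ac[seq_len(w)] / ac[1L]

  lags <- (min_period_px + 1L):(w %/% 2)
  # first prominent autocorrelation peak = the fundamental period
  peaks <- lags[which(
    ac[lags] > ac[lags - 1L] & ac[lags] >= ac[lags + 1L] & ac[lags] > 0.1
  )]
  if (length(peaks) == 0L) {
    stop("no periodic structure detected in the target image", call. = FALSE)
  }
  p0 <- peaks[1L]
  # parabolic sub-pixel refinement (lag p0 is 1-based index lag+1)
  y <- ac[c(p0 - 1L, p0, p0 + 1L) + 1L]
  denom <- y[1L] - 2 * y[2L] + y[3L]
  period_px <- p0 + if (abs(denom) > 0) 0.5 * (y[1L] - y[3L]) / denom else 0

  nm_per_px <- known_pitch_um * 1e3 / period_px
  structure(
    list(
      nm_per_px = nm_per_px,
      fov_um = c(width = w * nm_per_px / 1e3, height = h * nm_per_px / 1e3),
      period_px = period_px
    ),
    class = "vs_pixcal"
  )
}

#' @export
print.vs_pixcal <- function(x, ...) {
  cat(sprintf(
    "<vs_pixcal> %.2f nm/px; field of view %.1f um x %.1f um (period %.2f px)\n",
    x$nm_per_px, x$fov_um[["width"]], x$fov_um[["height"]], x$period_px
  ))
  invisible(x)
}
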