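## Image formation: specimen -> ideal intensity -> (coherent|incoherent)
## Gaussian blur -> radial distortion (applied in the sampling step) ->
## vignetting -> optional Bayer mosaic/demosaic -> sensor noise ->
## 8-bit quantization -> JPEG size model.

#' Render a frame from the virtual microscope
#'
#' Produces the image the camera would see for a given stage position,
#' optical train, specimen and sensor. Defocus is the distance between the
#' stage's physical z and the specimen's focal surface at the centre of the
#' field; the blur FWHM grows linearly with it
#' (`psf_fwhm_nm + defocus_blur_coeff * |dz|`). With noise disabled
#' (`read_noise_sigma = 0`, `shot_noise_scale = 0`) rendering is a pure,
#' bit-reproducible function of its inputs; with noise enabled it is a pure
#' function of the inputs and `seed`.
#'
#' @param stage a [stage_state()].
#' @param optics an [optics_config()].
#' @param specimen a [specimen_field()].
#' @param camera a [camera_config()].
#' @param seed integer seed for the sensor noise.
#' @param timestamp_s acquisition time recorded on the frame.
#' @return an object of class `vs_frame`: a list with `pixels` (matrix or
#'   `[h, w, 3]` array of counts 0-255), `true_position_nm`,
#'   `commanded_position_nm`, `timestamp_s`, `compressed_size_bytes`, and a
#'   `meta` list (blur FWHM, pixel pitch, seed).
#' @export
render_frame <- function(stage, optics, specimen, camera, seed = 1L,
                         timestamp_s = 0) {
  stopifnot(
    inherits(stage, "vs_stage"), inherits(optics, "vs_optics"),
    inherits(specimen, "vs_specimen"), inherits(camera, "vs_camera")
  )
  w <- camera$sensor_px[["width"]]
  h <- camera$sensor_px[["height"]]
  pitch <- optics$pixel_pitch_nm
  pos <- stage_position_nm(stage)

  dz <- abs(pos[["z"]] - focal_z_nm(specimen, pos[["x"]], pos[["y"]]))
  blur_fwhm <- optics$psf_fwhm_nm + optics$defocus_blur_coeff * dz
  sigma_px <- min(fwhm_to_sigma(blur_fwhm) / pitch, min(w, h) / 4)
  pad <- if (sigma_px >= 0.3) ceiling(3.5 * sigma_px) + 1L else 0L

  # padded 0-based pixel offsets from the image centre
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  u <- matrix((0:(w + 2 * pad - 1)) - pad - cx, h + 2 * pad, w + 2 * pad,
    byrow = TRUE
  )
  v <- matrix((0:(h + 2 * pad - 1)) - pad - cy, h + 2 * pad, w + 2 * pad)

  # radial distortion: an object point at normalized radius r appears at
  # r * (1 + k r^2); invert by fixed point to find which object point a
  # pixel samples
  k <- optics$distortion_k
  if (k != 0) {
    r_half_diag <- sqrt(cx^2 + cy^2)
    r_d <- sqrt(u^2 + v^2) / r_half_diag
    r_u <- r_d
    for (it in 1:6) r_u <- r_d / (1 + k * r_u^2)
    scale <- ifelse(r_d > 0, r_u / r_d, 1)
    u_s <- u * scale
    v_s <- v * scale
  } else {
    u_s <- u
    v_s <- v
  }

  x_s <- pos[["x"]] + u_s * pitch
  y_s <- pos[["y"]] - v_s * pitch

  half_extent <- specimen$extent_um * 1e3 / 2
  over <- max(max(abs(range(x_s))), max(abs(range(y_s)))) - half_extent
  if (over > 0) {
    stop(sprintf(
      paste0(
        "specimen extent (%g um) is smaller than the rendered field of ",
        "view: sampling extends %.1f um beyond the specimen edge"
      ),
      specimen$extent_um, over / 1e3
    ), call. = FALSE)
  }

  # soften primitive boundaries over one pixel pitch: point-sampling at
  # pixel centres then approximates the pixel-aperture integral, so a
  # boundary's sub-pixel position survives sampling instead of aliasing
  # to the grid
  ideal <- specimen_intensity(specimen, x_s, y_s, soft_nm = pitch)
  chans <- specimen$channels

  blur_one <- function(m) {
    if (sigma_px < 0.3) {
      return(m)
    }
    ksize <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
    kern <- EBImage::makeBrush(ksize, shape = "gaussian", sigma = sigma_px)
    EBImage::filter2(m, kern, boundary = "circular")
  }
  form_one <- function(m) {
    if (optics$edge_model == "coherent") {
      blur_one(sqrt(pmax(m, 0)))^2
    } else {
      blur_one(m)
    }
  }
  img <- if (chans == 1L) {
    form_one(ideal)
  } else {
    array(
      c(form_one(ideal[, , 1L]), form_one(ideal[, , 2L]),
        form_one(ideal[, , 3L])),
      dim(ideal)
    )
  }

  # crop the convolution padding
  rows <- (pad + 1L):(pad + h)
  cols <- (pad + 1L):(pad + w)
  img <- if (chans == 1L) img[rows, cols] else img[rows, cols, , drop = FALSE]

  # vignetting: gain 1 at centre, vignetting_falloff at the corners
  r2 <- (u[rows, cols]^2 + v[rows, cols]^2) / (cx^2 + cy^2)
  gain <- 1 - (1 - optics$vignetting_falloff) * r2
  counts <- if (chans == 1L) {
    img * gain * 255
  } else {
    array(apply(img, 3L, function(m) m * gain * 255), dim(img))
  }

  noisy <- camera$read_noise_sigma > 0 || camera$shot_noise_scale > 0
  if (chans == 3L && camera$bayer_enabled) {
    raw <- bayer_mosaic(counts)
    if (noisy) raw <- add_sensor_noise(raw, camera, seed)
    counts <- bayer_demosaic(raw)
  } else if (noisy) {
    counts <- add_sensor_noise(counts, camera, seed)
  }
  counts <- round(pmin(pmax(counts, 0), 255))

  pixels <- counts
  qual <- camera$compression_quality / 100
  bytes <- length(jpeg::writeJPEG(pixels / 255, raw(0), quality = qual))

  structure(
    list(
      pixels = pixels,
      true_position_nm = pos,
      commanded_position_nm = stage_position_nm(stage, "commanded"),
      timestamp_s = timestamp_s,
      compressed_size_bytes = bytes,
      meta = list(
        blur_fwhm_nm = blur_fwhm, pixel_pitch_nm = pitch, seed = seed,
        defocus_nm = dz
      )
    ),
    class = "vs_frame"
  )
}

## Gaussian approximation to shot + read noise, applied in counts.
add_sensor_noise <- function(counts, camera, seed) {
  sd <- sqrt(camera$shot_noise_scale^2 * pmax(counts, 0) +
    camera$read_noise_sigma^2)
  noise <- with_seed(seed, rnorm(length(counts)))
  counts + array(noise, dim(counts)) * sd
}

## RGGB mosaic: collapse an RGB array to the single-channel raw the sensor
## records (R at odd/odd, G at odd/even and even/odd, B at even/even,
## 1-based row/col).
bayer_mosaic <- function(rgb) {
  h <- dim(rgb)[1L]
  w <- dim(rgb)[2L]
  odd_r <- (seq_len(h) %% 2L) == 1L
  odd_c <- (seq_len(w) %% 2L) == 1L
  raw <- matrix(0, h, w)
  raw[odd_r, odd_c] <- rgb[, , 1L][odd_r, odd_c]
  raw[odd_r, !odd_c] <- rgb[, , 2L][odd_r, !odd_c]
  raw[!odd_r, odd_c] <- rgb[, , 2L][!odd_r, odd_c]
  raw[!odd_r, !odd_c] <- rgb[, , 3L][!odd_r, !odd_c]
  raw
}

## Bilinear demosaic of an RGGB raw frame back to RGB.
bayer_demosaic <- function(raw) {
  h <- nrow(raw)
  w <- ncol(raw)
  odd_r <- (seq_len(h) %% 2L) == 1L
  odd_c <- (seq_len(w) %% 2L) == 1L
  masks <- list(
    R = outer(odd_r, odd_c),
    G = outer(odd_r, !odd_c) | outer(!odd_r, odd_c),
    B = outer(!odd_r, !odd_c)
  )
  k_rb <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 4
  k_g <- matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0), 3, 3) / 4
  interp <- function(mask, kern) {
    sparse <- raw * mask
    num <- EBImage::filter2(sparse, kern, boundary = "circular")
    den <- EBImage::filter2(mask * 1, kern, boundary = "circular")
    num / pmax(den, 1e-9)
  }
  array(
    c(interp(masks$R, k_rb), interp(masks$G, k_g), interp(masks$B, k_rb)),
    c(h, w, 3L)
  )
}
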