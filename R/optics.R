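#' Optical train configuration
#'
#' Describes the imaging optics of the virtual microscope: an in-focus
#' amplitude point-spread function of Gaussian shape parameterized by its
#' full width at half maximum, a linear growth of blur width with defocus,
#' radial vignetting, and a single-coefficient axisymmetric radial
#' distortion.
#'
#' @param numerical_aperture objective NA (bookkeeping; resolution is set
#'   directly by `psf_fwhm_nm`).
#' @param wavelength_nm nominal illumination wavelength.
#' @param psf_fwhm_nm in-focus amplitude-PSF full width at half maximum, nm.
#' @param pixel_pitch_nm sample-plane distance per pixel, nm.
#' @param defocus_blur_coeff added blur FWHM per nm of defocus
#'   (dimensionless); the blur at defocus `dz` is
#'   `psf_fwhm_nm + defocus_blur_coeff * |dz|`.
#' @param vignetting_falloff relative intensity at the image corner, in
#'   (0, 1]; the gain is 1 at the centre and falls off quadratically with
#'   radius.
#' @param distortion_k radial distortion coefficient: a point at normalized
#'   radius r (r = 1 at the image half-diagonal) appears at
#'   `r * (1 + distortion_k * r^2)`.
#' @param edge_model `"coherent"` (the specimen's amplitude, the square
#'   root of its intensity, is convolved with the PSF and then squared) or
#'   `"incoherent"` (intensity convolved directly).
#' @return an object of class `vs_optics`.
#' @export
optics_config <- function(numerical_aperture = 0.65,
                          wavelength_nm = 550,
                          psf_fwhm_nm = 480,
                          pixel_pitch_nm = 100,
                          defocus_blur_coeff = 0.5,
                          vignetting_falloff = 0.7,
                          distortion_k = 0,
                          edge_model = c("coherent", "incoherent")) {
  edge_model <- match.arg(edge_model)
  stopifnot(
    psf_fwhm_nm > 0, pixel_pitch_nm > 0, defocus_blur_coeff >= 0,
    vignetting_falloff > 0, vignetting_falloff <= 1
  )
  structure(
    list(
      numerical_aperture = numerical_aperture,
      wavelength_nm = wavelength_nm,
      psf_fwhm_nm = psf_fwhm_nm,
      pixel_pitch_nm = pixel_pitch_nm,
      defocus_blur_coeff = defocus_blur_coeff,
      vignetting_falloff = vignetting_falloff,
      distortion_k = distortion_k,
      edge_model = edge_model
    ),
    class = "vs_optics"
  )
}

#' Named optics presets
#'
#' `"0.65NA-dry"` is a 40x Plan-corrected dry objective with an in-focus
#' amplitude-PSF FWHM of 480 nm at a sample-plane pixel pitch of 100 nm;
#' `"1.25NA-oil"` is a 100x oil-immersion objective used for high-resolution
#' smear imaging.
#'
#' @param name preset name.
#' @param ... overrides passed on to [optics_config()].
#' @return an object of class `vs_optics`.
#' @export
optics_preset <- function(name = c("0.65NA-dry", "1.25NA-oil"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "0.65NA-dry" = list(
      numerical_aperture = 0.65, psf_fwhm_nm = 480, pixel_pitch_nm = 100,
      defocus_blur_coeff = 0.5
    ),
    "1.25NA-oil" = list(
      numerical_aperture = 1.25, psf_fwhm_nm = 260, pixel_pitch_nm = 50,
      defocus_blur_coeff = 0.9
    )
  )
  do.call(optics_config, modifyList(base, list(...)))
}

#' Camera / sensor configuration
#'
#' An 8-bit sensor with Gaussian read noise, square-root (shot) noise, an
#' optional Bayer colour mosaic (sampled RGGB then bilinearly demosaiced),
#' and a compressed-stream model: every frame is JPEG-encoded once at
#' `compression_quality` and the resulting byte count is recorded on the
#' frame.
#'
#' The default sensor is a scaled-down 820 x 616 version of an 8-megapixel
#' 3280 x 2464 CMOS sensor; pass `sensor_px = c(3280, 2464)` for the full
#' size.
#'
#' @param sensor_px width x height in pixels.
#' @param bit_depth bits per sample (only 8 is supported).
#' @param read_noise_sigma Gaussian read noise, in counts.
#' @param shot_noise_scale scale of the signal-dependent noise: the shot
#'   component has standard deviation `shot_noise_scale * sqrt(counts)`.
#' @param bayer_enabled simulate a Bayer colour filter array (RGB scenes
#'   only).
#' @param compression_quality JPEG quality, 1-100, for the
#'   compressed-frame-size model.
#' @param fps frame rate of the video stream, used by the simulator clock
#'   and the fast autofocus.
#' @return an object of class `vs_camera`.
#' @export
camera_config <- function(sensor_px = c(820, 616),
                          bit_depth = 8,
                          read_noise_sigma = 1.0,
                          shot_noise_scale = 0.2,
                          bayer_enabled = FALSE,
                          compression_quality = 75,
                          fps = 10) {
  stopifnot(
    length(sensor_px) == 2L, all(sensor_px >= 3), bit_depth == 8,
    read_noise_sigma >= 0, shot_noise_scale >= 0,
    compression_quality >= 1, compression_quality <= 100, fps > 0
  )
  structure(
    list(
      sensor_px = c(width = as.integer(sensor_px[[1L]]),
                    height = as.integer(sensor_px[[2L]])),
      bit_depth = 8L,
      read_noise_sigma = read_noise_sigma,
      shot_noise_scale = shot_noise_scale,
      bayer_enabled = isTRUE(bayer_enabled),
      compression_quality = as.integer(compression_quality),
      fps = fps
    ),
    class = "vs_camera"
  )
}
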