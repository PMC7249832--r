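# Knife-edge pipeline: edge-spread profile -> sqrt -> derivative -> FWHM.

make_erf_edge <- function(h = 200, w = 160, sigma_nm = 300, pitch_nm = 100,
                          angle_deg = 1, lo = 0.05, hi = 0.95) {
  # continuous-valued incoherent edge image: intensity is an error
  # function of known width, no noise, no quantization
  slope <- tan(angle_deg * pi / 180)
  x0 <- (w - 1) / 2
  vals <- outer(seq_len(h), seq_len(w), function(r, c) {
    d <- ((c - 1) - x0 - slope * (r - h / 2)) * pitch_nm
    lo + (hi - lo) * pnorm(d / sigma_nm)
  })
  vals * 255
}

test_that("a perfect step edge yields a step profile within a pixel pitch", {
  # ideal step seen through the pixel aperture: each pixel integrates
  # the step over its 1 px footprint, giving a ramp inside one pixel
  h <- 200
  w <- 120
  slope <- tan(1 * pi / 180)
  m <- outer(seq_len(h), seq_len(w), function(r, c) {
    d <- (c - 1) - (w - 1) / 2 - slope * (r - h / 2)
    13 + (242 - 13) * pmin(pmax(d + 0.5, 0), 1)
  })
  esf <- extract_edge_profile(m, pitch_nm = 100)
  width_25_75 <- diff(approx(esf$values, esf$positions_nm, c(0.25, 0.75),
    ties = "ordered"
  )$y)
  expect_lt(width_25_75, 150)

  # its PSF hits the discretization floor: FWHM no more than 2 pitches
  psf <- psf_from_edge(esf)
  expect_lte(psf$fwhm_nm, 200)
})

test_that("a Gaussian edge of known width matches the error-function form", {
  sigma <- 300
  m <- make_erf_edge(sigma_nm = sigma)
  esf <- extract_edge_profile(m, pitch_nm = 100)
  ref <- pnorm(esf$positions_nm / sigma)
  keep <- abs(esf$positions_nm) < 1500
  expect_lt(max(abs(esf$values[keep] - ref[keep])), 0.01)
})

test_that("row pooling under edge tilt achieves sub-pixel sampling", {
  cam <- cam_noiseless(c(200, 200))
  fwhm_of <- function(angle) {
    spec <- specimen_knife_edge(angle_deg = angle)
    mic <- virtual_microscope(spec, optics = optics_plain(), camera = cam)
    psf_from_edge(extract_edge_profile(mic_capture(mic)))$fwhm_nm
  }
  f_tilt <- fwhm_of(1)
  f_flat <- fwhm_of(0)
  expect_equal(f_tilt, f_flat, tolerance = 0.04)
  expect_equal(f_tilt, 480, tolerance = 0.05)
})

test_that("the estimator is unbiased across configured widths with noise on", {
  spec <- specimen_knife_edge(angle_deg = 1)
  for (width in c(300, 480, 1000)) {
    mic <- virtual_microscope(
      spec,
      optics = optics_preset("0.65NA-dry", psf_fwhm_nm = width),
      camera = camera_config(c(600, 450)), seed = 11
    )
    est <- psf_from_edge(extract_edge_profile(mic_capture(mic)))$fwhm_nm
    expect_equal(est, width, tolerance = 0.05)
  }
})

test_that("doubling the configured width doubles the recovered width", {
  spec <- specimen_knife_edge(angle_deg = 1)
  est <- vapply(c(480, 960), function(wd) {
    mic <- virtual_microscope(
      spec,
      optics = optics_preset("0.65NA-dry", psf_fwhm_nm = wd),
      camera = camera_config(c(600, 450)), seed = 5
    )
    psf_from_edge(extract_edge_profile(mic_capture(mic)))$fwhm_nm
  }, numeric(1))
  expect_equal(est[2] / est[1], 2, tolerance = 0.05)
})

test_that("widths below twice the pixel pitch hit the reported floor", {
  spec <- specimen_knife_edge(angle_deg = 1)
  mic <- virtual_microscope(
    spec,
    optics = optics_preset("0.65NA-dry", psf_fwhm_nm = 100),
    camera = cam_noiseless(c(300, 240))
  )
  est <- psf_from_edge(extract_edge_profile(mic_capture(mic)))$fwhm_nm
  # accuracy degrades at the sampling floor, but a width is still
  # reported rather than failing silently
  expect_gt(est, 50)
  expect_lt(est, 260)
})

test_that("images without a detectable edge are rejected", {
  expect_error(
    extract_edge_profile(matrix(128, 100, 100), pitch_nm = 100),
    "edge not detected"
  )
})
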