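# Sampling check, pixel-size calibration, and lens-shading correction.

test_that("sampling verdict compares the effective Bayer block to resolution", {
  r <- sampling_check(100, 480, bayer_enabled = TRUE)
  expect_equal(r$effective_pitch_nm, 200)
  expect_true(r$adequately_sampled)

  expect_equal(sampling_check(100, 480, FALSE)$effective_pitch_nm, 100)

  r2 <- sampling_check(160, 300, bayer_enabled = TRUE)
  expect_equal(r2$effective_pitch_nm, 320)
  expect_false(r2$adequately_sampled)
  expect_match(r2$verdict, "undersampled")
})

test_that("pixel size is recovered from a grid of known pitch", {
  mic <- virtual_microscope(
    specimen_grid(pitch_um = 10),
    optics = optics_plain(), camera = camera_config(c(400, 300)), seed = 2
  )
  cal <- calibrate_pixel_size(mic_capture(mic), known_pitch_um = 10)
  expect_equal(cal$nm_per_px, 100, tolerance = 0.01)
  expect_equal(cal$fov_um[["width"]], 40, tolerance = 0.01)

  # doubling the target pitch doubles the measured period, same nm/px
  mic2 <- virtual_microscope(
    specimen_grid(pitch_um = 20),
    optics = optics_plain(), camera = camera_config(c(400, 300)), seed = 2
  )
  cal2 <- calibrate_pixel_size(mic_capture(mic2), known_pitch_um = 20)
  expect_equal(cal2$period_px / cal$period_px, 2, tolerance = 0.02)
  expect_equal(cal2$nm_per_px, cal$nm_per_px, tolerance = 0.02)

  # full-resolution bookkeeping: 3280 x 2464 at 106.7 nm/px is the
  # 350 um x 263 um field of view
  fov <- c(3280, 2464) * 106.7 / 1e3
  expect_equal(fov[1], 350, tolerance = 0.004)
  expect_equal(fov[2], 262.9, tolerance = 0.004)

  expect_error(
    calibrate_pixel_size(matrix(128, 200, 200), known_pitch_um = 10),
    "no periodic"
  )
})

test_that("shading table inverts the configured vignetting", {
  opt <- optics_preset("0.65NA-dry", vignetting_falloff = 0.7)
  mic <- virtual_microscope(specimen_flat(0.85),
    optics = opt,
    camera = camera_config(c(320, 240)), seed = 4
  )
  tab <- build_shading_table(mic_capture(mic))
  expect_equal(min(tab$gains), 1) # centre-normalized
  # corner-cell gain equals the model inverse at the corner cell centre
  w <- 320
  h <- 240
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  ccx <- (0.5 / 32) * w - 0.5
  ccy <- (0.5 / 24) * h - 0.5
  r2 <- ((ccx - cx)^2 + (ccy - cy)^2) / (cx^2 + cy^2)
  expect_equal(tab$gains[1, 1, 1], 1 / (1 - 0.3 * r2), tolerance = 0.02)
  # and approaches 1 / 0.7 towards the true corner
  expect_equal(max(tab$gains), 1 / 0.7, tolerance = 0.05)
})

test_that("build-then-apply flattens an independent noisy flat field", {
  opt <- optics_preset("0.65NA-dry", vignetting_falloff = 0.7)
  mic <- virtual_microscope(specimen_flat(0.85),
    optics = opt,
    camera = camera_config(c(320, 240)), seed = 4
  )
  tab <- build_shading_table(mic_capture(mic))
  second <- mic_capture(mic) # independent noise realization
  corrected <- apply_shading_correction(second, tab)
  expect_lt(flatness_rms(corrected), 0.01)
  expect_gt(flatness_rms(second$pixels), 0.02) # uncorrected is not flat

  # an all-ones table is the identity
  ones <- tab
  ones$gains[] <- 1
  out <- apply_shading_correction(second, ones)
  expect_equal(unclass(out), second$pixels, ignore_attr = TRUE)
})

test_that("correction amplifies corner noise by roughly the gain ratio", {
  opt <- optics_preset("0.65NA-dry", vignetting_falloff = 0.7)
  mic <- virtual_microscope(specimen_flat(0.85),
    optics = opt,
    camera = camera_config(c(320, 240)), seed = 4
  )
  tab <- build_shading_table(mic_capture(mic))
  # noise maps: sd over an ensemble of corrected frames, corner vs centre
  frames <- lapply(1:6, function(i) {
    apply_shading_correction(mic_capture(mic), tab)
  })
  arr <- simplify2array(frames)
  sd_map <- apply(arr, c(1, 2), sd)
  corner_sd <- mean(sd_map[1:20, 1:20])
  centre_sd <- mean(sd_map[111:130, 151:170])
  gain_ratio <- tab$gains[1, 1, 1] / min(tab$gains)
  expect_equal(corner_sd / centre_sd, gain_ratio, tolerance = 0.25)
})

test_that("dark flat fields abort the shading calibration", {
  m <- matrix(200, 120, 160)
  m[1:10, 1:10] <- 2 # a nearly black corner cell
  expect_error(build_shading_table(m, grid_dims = c(16, 12)), "illumination")
})
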