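test_that("sweep recovers a focal plane between samples within half a spacing", {
  spec <- smear_tilted(c_nm = 1200, seed = 3)
  mic <- virtual_microscope(spec, camera = cam_small(), seed = 5)
  res <- autofocus_sweep(mic, c(-8000, 8000), n_points = 11)
  spacing <- 16000 / 10
  expect_false(res$at_boundary)
  expect_lt(abs(res$best_z_nm - 1200), spacing / 2)
  # the stage is left at the found focus
  expect_equal(mic_position(mic, "commanded")[["z"]],
    res$best_z_nm,
    tolerance = 50
  )
  # samples cover the requested range in order
  expect_equal(nrow(res$samples), 11)
  expect_true(!is.unsorted(res$samples$z_nm))
})

test_that("a peak exactly at a sampled position is returned exactly", {
  # synthetic camera: score curve with maximum at a sampled z
  spec <- smear_tilted(c_nm = 0, seed = 3)
  mic <- virtual_microscope(spec, camera = cam_noiseless(), seed = 1)
  res <- autofocus_sweep(mic, c(-4000, 4000), n_points = 9)
  # spacing 1000 nm; z* = 0 is the middle sample; refinement is symmetric
  expect_lt(abs(res$best_z_nm), 350)
})

test_that("monotone sharpness over the range sets the boundary flag", {
  # focus just above the swept range: sharpness rises towards the end
  spec <- smear_tilted(c_nm = 4500, seed = 3)
  mic <- virtual_microscope(spec, camera = cam_small(), seed = 8)
  res <- autofocus_sweep(mic, c(-6000, 3000), n_points = 7)
  expect_true(res$at_boundary)
  expect_equal(res$best_z_nm, 3000)
})

test_that("sweep result does not depend on the approach direction", {
  spec <- smear_tilted(c_nm = 1200, seed = 3)
  st_b <- stage_state(backlash_steps = c(x = 0, y = 0, z = 10))
  mic_lo <- virtual_microscope(spec,
    camera = cam_small(),
    stage = move_to(st_b, c(z = -9000)), seed = 5
  )
  mic_hi <- virtual_microscope(spec,
    camera = cam_small(),
    stage = move_to(st_b, c(z = 9000)), seed = 5
  )
  r_lo <- autofocus_sweep(mic_lo, c(-8000, 8000), n_points = 11)
  r_hi <- autofocus_sweep(mic_hi, c(-8000, 8000), n_points = 11)
  expect_equal(r_lo$best_z_nm, r_hi$best_z_nm, tolerance = 100)
})

test_that("compressed-size autofocus agrees with the sharpness sweep", {
  spec <- smear_tilted(c_nm = 1200, seed = 3)
  mic_a <- virtual_microscope(spec, camera = cam_small(), seed = 5)
  sweep <- autofocus_sweep(mic_a, c(-8000, 8000), n_points = 11)
  mic_b <- virtual_microscope(spec, camera = cam_small(), seed = 6)
  fast <- jpeg_fast_autofocus(mic_b, c(-8000, 8000), speed_nm_per_s = 16000)
  spacing <- 16000 / 10
  expect_equal(fast$method, "jpeg_fast")
  expect_lt(abs(fast$best_z_nm - sweep$best_z_nm), spacing)
  expect_true(all(fast$samples$frame_bytes > 0))
  # single continuous pass: each commanded z visited once, ascending
  expect_true(!is.unsorted(fast$samples$z_nm))
  expect_equal(anyDuplicated(fast$samples$z_nm), 0)
})

test_that("doubling the pass speed halves the samples but still finds focus", {
  spec <- smear_tilted(c_nm = 1200, seed = 3)
  mic_1 <- virtual_microscope(spec, camera = cam_small(), seed = 6)
  slow <- jpeg_fast_autofocus(mic_1, c(-8000, 8000), speed_nm_per_s = 8000)
  mic_2 <- virtual_microscope(spec, camera = cam_small(), seed = 6)
  fast <- jpeg_fast_autofocus(mic_2, c(-8000, 8000), speed_nm_per_s = 16000)
  expect_equal(nrow(slow$samples) / nrow(fast$samples), 2, tolerance = 0.15)
  fast_spacing <- 16000 / 10
  expect_lt(abs(fast$best_z_nm - 1200), 2 * fast_spacing)
})

test_that("featureless scenes and too-fast passes are reported as errors", {
  mic <- virtual_microscope(specimen_flat(0.9), camera = cam_small(), seed = 7)
  expect_error(
    jpeg_fast_autofocus(mic, c(-8000, 8000), speed_nm_per_s = 16000),
    "no focus found"
  )
  mic2 <- virtual_microscope(smear_tilted(), camera = cam_small(), seed = 7)
  expect_error(
    jpeg_fast_autofocus(mic2, c(-2000, 2000), speed_nm_per_s = 4e6),
    "fewer than 5"
  )
})
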