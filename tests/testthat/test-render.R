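test_that("rendering is deterministic: same inputs give bit-identical frames", {
  spec <- smear_tilted()
  st <- stage_state()
  cam <- cam_small()
  f1 <- render_frame(st, optics_plain(), spec, cam, seed = 9)
  f2 <- render_frame(st, optics_plain(), spec, cam, seed = 9)
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(f1$compressed_size_bytes, f2$compressed_size_bytes)

  # different seed, different noise
  f3 <- render_frame(st, optics_plain(), spec, cam, seed = 10)
  expect_false(identical(f1$pixels, f3$pixels))

  # noise disabled: identical regardless of seed
  f4 <- render_frame(st, optics_plain(), spec, cam_noiseless(), seed = 1)
  f5 <- render_frame(st, optics_plain(), spec, cam_noiseless(), seed = 2)
  expect_identical(f4$pixels, f5$pixels)
})

test_that("vignetting gain is 1 at centre and falls to the configured corner value", {
  opt <- optics_preset("0.65NA-dry", vignetting_falloff = 0.7)
  fr <- render_frame(
    stage_state(), opt, specimen_flat(0.9), cam_noiseless(c(200, 150))
  )
  m <- fr$pixels
  centre <- mean(m[74:77, 99:102])
  corner <- m[1, 1]
  expect_equal(centre / corner, 1 / 0.7, tolerance = 0.02)
})

test_that("defocus reduces sharpness; the response is unimodal in z", {
  spec <- smear_tilted(c_nm = 0, seed = 3)
  st <- stage_state()
  opt <- optics_plain()
  cam <- cam_noiseless()
  score_at <- function(z) {
    fr <- render_frame(move_to(st, c(z = z)), opt, spec, cam)
    # score the binned preview, as the autofocus consumes frames;
    # full-resolution scores at extreme defocus are dominated by 8-bit
    # quantization contouring
    laplacian_sharpness(virtuscope:::bin_image(fr$pixels, 4))
  }
  zs <- seq(-6000, 6000, by = 1500)
  scores <- vapply(zs, score_at, numeric(1))
  peak <- which.max(scores)
  expect_equal(zs[peak], 0)
  # unimodal: non-increasing away from the peak
  expect_true(all(diff(scores[peak:length(scores)]) <= 1e-9))
  expect_true(all(diff(scores[1:peak]) >= -1e-9))
})

test_that("a specimen smaller than the field of view is a render error", {
  tiny <- specimen_flat(0.9, extent_um = 10)
  expect_error(
    render_frame(stage_state(), optics_plain(), tiny, cam_small()),
    "extent"
  )
})

test_that("compressed size equals a real JPEG encoding of the frame", {
  fr <- render_frame(
    stage_state(), optics_plain(), smear_tilted(c_nm = 0), cam_small(),
    seed = 2
  )
  expect_equal(
    fr$compressed_size_bytes,
    length(jpeg::writeJPEG(fr$pixels / 255, raw(0), quality = 0.75))
  )
  expect_gt(fr$compressed_size_bytes, 0)
})

test_that("distortion-free optics render straight lines straight", {
  # the rendered knife edge stays at a constant column across all rows
  spec <- specimen_knife_edge(edge_x_um = 0, angle_deg = 0, extent_um = 200)
  st <- move_to(stage_state(), c(x = 7000))
  fr <- render_frame(st, optics_plain(), spec, cam_noiseless(c(400, 300)))
  cr <- virtuscope:::row_edge_crossings(fr$pixels)
  expect_true(all(!is.na(cr$crossing_px)))
  expect_lt(diff(range(cr$crossing_px)), 0.2)
})
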