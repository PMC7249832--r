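test_that("phase correlation finds known integer shifts", {
  set.seed(8)
  base <- matrix(runif(120 * 120, 0, 255), 120, 120)
  shift_img <- function(m, dy, dx) {
    h <- nrow(m)
    w <- ncol(m)
    out <- matrix(mean(m), h, w)
    src_r <- seq_len(h) - dy
    src_c <- seq_len(w) - dx
    ok_r <- src_r >= 1 & src_r <= h
    ok_c <- src_c >= 1 & src_c <= w
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  for (shift in list(c(0, 0), c(3, -2), c(-5, 4))) {
    b <- shift_img(base, shift[1], shift[2])
    pc <- phase_correlate(base, b)
    expect_equal(unname(pc$shift), shift)
    expect_gt(pc$peak, 0.1)
  }
})

test_that("a single tile stitches to its own central crop", {
  spec <- smear_tilted(c_nm = 0, seed = 31)
  mic <- virtual_microscope(spec, camera = cam_noiseless(c(160, 120)))
  ts <- execute_scan(plan_grid_scan(1, 1, fov_um = c(16, 12)), mic)
  mos <- stitch_tiles(ts, crop_margin_fraction = 0.25)
  px <- ts$tiles[[1]]$frame$pixels
  expect_identical(mos$image, px[31:90, 41:120])
})

test_that("tile jitter is recovered to within a pixel", {
  # tiles rendered at true positions = nominal + jitter, while the
  # manifest claims the nominal grid: the stitcher must find the truth
  opt <- optics_plain()
  cam <- cam_noiseless(c(160, 120))
  spec <- specimen_blood_smear(region_um = 150, seed = 31, extent_um = 400)
  plan <- plan_grid_scan(2, 2, overlap_fraction = 0.5, fov_um = c(16, 12))
  set.seed(14)
  jit <- matrix(sample(-3:3, 8, replace = TRUE), 4, 2) * 100 # whole pixels
  tiles <- lapply(seq_along(plan$sites), function(s_idx) {
    site <- plan$sites[[s_idx]]
    st <- move_to(stage_state(), c(
      x = site$target_xy_nm[["x"]] + jit[s_idx, 1],
      y = site$target_xy_nm[["y"]] + jit[s_idx, 2]
    ))
    fr <- render_frame(st, opt, spec, cam)
    list(
      frame = fr, site_index = s_idx, grid_index = site$grid_index,
      site_xy_nm = site$target_xy_nm, z_offset_nm = 0, focus_z_nm = 0,
      focus = NULL
    )
  })
  ts <- structure(
    list(tiles = tiles, manifest = NULL, plan = plan, pixel_pitch_nm = 100),
    class = "vs_tileset"
  )
  mos <- stitch_tiles(ts, crop_margin_fraction = 0.25)
  expect_equal(nrow(mos$flagged_pairs), 0)
  off <- mos$recovered_offsets_px
  # stage jitter +x shifts the tile origin +x in mosaic columns, +y
  # (up) shifts it to smaller row numbers
  expected_col <- off$nominal_col_px + jit[, 1] / 100
  expected_row <- off$nominal_row_px - jit[, 2] / 100
  # positions are relative to the anchored first tile
  expect_true(all(abs(
    (off$col_px - off$col_px[1]) - (expected_col - expected_col[1])
  ) <= 1))
  expect_true(all(abs(
    (off$row_px - off$row_px[1]) - (expected_row - expected_row[1])
  ) <= 1))
})

test_that("zero-jitter noiseless tiles reproduce the specimen raster exactly", {
  # geometry chosen so stage steps (70 nm) and pixels (100 nm) align:
  # tile spacing 7000 nm is 100 steps and 70 px
  opt <- optics_config(
    psf_fwhm_nm = 480, pixel_pitch_nm = 100, vignetting_falloff = 1,
    distortion_k = 0
  )
  cam <- cam_noiseless(c(140, 140))
  spec <- specimen_blood_smear(region_um = 120, seed = 31, extent_um = 400)
  mic <- virtual_microscope(spec, optics = opt, camera = cam)
  ts <- execute_scan(
    plan_grid_scan(2, 2, overlap_fraction = 0.5, fov_um = c(14, 14)), mic
  )
  mos <- stitch_tiles(ts, crop_margin_fraction = 0.25)

  gt <- render_frame(stage_state(), opt, spec, cam_noiseless(c(210, 210)))
  off <- mos$recovered_offsets_px
  mr <- round(0.25 * 140)
  r0 <- min(off$row_px) + mr
  c0 <- min(off$col_px) + mr
  sub <- gt$pixels[(r0 + 1):(r0 + nrow(mos$image)),
                   (c0 + 1):(c0 + ncol(mos$image))]
  expect_identical(mos$image, sub)

  # mosaic bounding box matches the closed form from positions and crop
  ch <- 140 - 2 * mr
  expect_equal(nrow(mos$image), diff(range(off$row_px)) + ch)
  expect_equal(ncol(mos$image), diff(range(off$col_px)) + ch)
})

test_that("tile sets round-trip through the manifest on disk", {
  spec <- smear_tilted(c_nm = 0, seed = 31)
  mic <- virtual_microscope(spec, camera = cam_noiseless(c(120, 100)))
  ts <- execute_scan(
    plan_grid_scan(2, 1, overlap_fraction = 0.5, fov_um = c(12, 10)), mic
  )
  dir <- withr::local_tempdir()
  write_tileset(ts, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ts2 <- read_tileset(dir)
  expect_length(ts2$tiles, 2)
  expect_equal(ts2$tiles[[1]]$frame$pixels, ts$tiles[[1]]$frame$pixels)
  mos1 <- stitch_tiles(ts, crop_margin_fraction = 0.2)
  mos2 <- stitch_tiles(ts2, crop_margin_fraction = 0.2)
  expect_equal(mos1$image, mos2$image)
})
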