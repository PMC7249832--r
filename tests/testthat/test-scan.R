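test_that("grid plans have the right geometry and capture count", {
  plan <- plan_grid_scan(10, 10, nz = 5, dz_nm = 500, fov_um = c(82, 61.6))
  expect_equal(n_captures(plan), 500)
  expect_length(plan$sites, 100)
  expect_equal(plan$sites[[1]]$z_offsets_nm, c(-1000, -500, 0, 500, 1000))

  # single capture at the origin
  p1 <- plan_grid_scan(1, 1, fov_um = c(82, 61.6))
  expect_equal(n_captures(p1), 1)
  expect_equal(unname(p1$sites[[1]]$target_xy_nm), c(0, 0))

  # 20% overlap of a 350 um field gives 280 um spacing
  p2 <- plan_grid_scan(2, 1, overlap_fraction = 0.2, fov_um = c(350, 262))
  dx <- p2$sites[[2]]$target_xy_nm[["x"]] - p2$sites[[1]]$target_xy_nm[["x"]]
  expect_equal(dx, 280e3)

  # plans beyond the stage travel are rejected with the offending sites
  expect_error(
    plan_grid_scan(40, 1, overlap_fraction = 0, fov_um = c(350, 262)),
    "travel"
  )
})

test_that("snake ordering travels less than raster on any multi-row grid", {
  for (dims in list(c(2, 2), c(3, 4), c(5, 3))) {
    snake <- plan_grid_scan(dims[1], dims[2],
      fov_um = c(82, 61.6), order = "snake"
    )
    raster <- plan_grid_scan(dims[1], dims[2],
      fov_um = c(82, 61.6), order = "raster"
    )
    expect_lt(plan_travel_nm(snake), plan_travel_nm(raster))
  }
})

test_that("per-site autofocus keeps every tile near the in-focus blur", {
  spec <- specimen_blood_smear(
    region_um = 400, focal_surface = c(a = 0.01, b = 0, c = 500), seed = 11
  )
  mic <- virtual_microscope(spec, camera = camera_config(c(160, 120)), seed = 9)
  plan <- plan_grid_scan(3, 3,
    overlap_fraction = 0.2, fov_um = c(16, 12),
    autofocus_policy = "laplacian"
  )
  ts <- execute_scan(plan, mic, af_range_nm = 16000, af_points = 11)
  expect_equal(nrow(ts$manifest), n_captures(plan))
  blur <- vapply(ts$tiles, function(t) t$frame$meta$blur_fwhm_nm, numeric(1))
  expect_lt(max(blur), 1.1 * 480)

  # negative control: without autofocus the tilted plane defocuses tiles
  mic0 <- virtual_microscope(spec, camera = camera_config(c(160, 120)), seed = 10)
  plan0 <- plan_grid_scan(3, 3,
    overlap_fraction = 0.2, fov_um = c(16, 12),
    autofocus_policy = "none"
  )
  ts0 <- execute_scan(plan0, mic0)
  blur0 <- vapply(ts0$tiles, function(t) t$frame$meta$blur_fwhm_nm, numeric(1))
  expect_gt(max(blur0), 1.3 * 480)
})

test_that("capture count is conserved for stacked scans", {
  spec <- smear_tilted(c_nm = 0)
  mic <- virtual_microscope(spec, camera = cam_noiseless(c(80, 60)))
  plan <- plan_grid_scan(2, 2,
    nz = 3, dz_nm = 500, overlap_fraction = 0.2,
    fov_um = c(8, 6)
  )
  ts <- execute_scan(plan, mic)
  expect_length(ts$tiles, 12)
  expect_equal(nrow(ts$manifest), 12)
  # every tile records the z it was taken at
  expect_true(all(is.finite(ts$manifest$z_commanded_nm)))
  # stack offsets are applied relative to the site focus
  t1 <- ts$tiles[1:3]
  zs <- vapply(t1, function(t) t$frame$commanded_position_nm[["z"]], numeric(1))
  expect_equal(diff(zs), c(500, 500), tolerance = 26)
})

test_that("time-lapse autofocus bounds drift-induced focus error", {
  run_tl <- function(autofocus) {
    spec <- smear_tilted(c_nm = 0, seed = 3)
    # 3 um/h of z drift, hourly captures over 3 hours
    st <- stage_state(drift_rate_nm_per_hour = c(x = 0, y = 0, z = 3000))
    mic <- virtual_microscope(spec,
      camera = camera_config(c(160, 120)),
      stage = st, seed = 12
    )
    plan <- plan_timelapse(4, interval_s = 3600,
      autofocus_before_capture = autofocus
    )
    ts <- execute_scan(plan, mic, af_range_nm = 30000, af_points = 11)
    vapply(ts$tiles, function(t) t$frame$meta$defocus_nm, numeric(1))
  }
  defocus_off <- run_tl(FALSE)
  expect_gt(defocus_off[4], 5000) # ~9 um of accumulated drift
  expect_gt(defocus_off[4], defocus_off[2]) # grows with elapsed time
  defocus_on <- run_tl(TRUE)
  expect_lt(defocus_on[4], 1000) # bounded by the sweep resolution

  p1 <- plan_timelapse(1, interval_s = 5)
  expect_equal(n_captures(p1), 1)
})
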