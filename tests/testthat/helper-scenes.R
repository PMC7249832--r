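# Shared fixtures, all generated in code. Small sensors keep renders fast;
# the noiseless camera isolates geometric/optical behaviour from sensor
# noise where a test is about the former.

cam_small <- function(...) camera_config(c(240, 180), ...)

cam_noiseless <- function(sensor_px = c(240, 180)) {
  camera_config(sensor_px, read_noise_sigma = 0, shot_noise_scale = 0)
}

optics_plain <- function(...) {
  # unit vignetting and no distortion unless a test asks for them
  optics_preset("0.65NA-dry", vignetting_falloff = 1, distortion_k = 0, ...)
}

smear_tilted <- function(c_nm = 1200, a = 0, seed = 3, region_um = 300) {
  specimen_blood_smear(
    region_um = region_um,
    focal_surface = c(a = a, b = 0, c = c_nm), seed = seed
  )
}
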