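# A thin blood-smear-like specimen under the 40x 0.65 NA dry preset, on a
# slightly tilted slide. The default camera is the scaled-down 820x616
# sensor; pass camera: {sensor_px: [3280, 2464]} for the full-size chip.
specimen:
  type: blood_smear
  region_um: 400
  focal_surface:
    a: 0.005
    b: 0.0
    c: 800.0
optics:
  preset: 0.65NA-dry
camera:
  sensor_px: [400, 300]
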