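# Near-vertical knife edge for resolution (edge-spread) measurements.
specimen:
  type: knife_edge
  angle_deg: 1
optics:
  preset: 0.65NA-dry
camera:
  sensor_px: [820, 616]
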