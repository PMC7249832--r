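# Example run configuration. Lengths always carry a unit suffix.
scene:
  type: blood_smear
optics:
  preset: 0.65NA-dry
scan:
  nx: 3
  ny: 3
  nz: 5
  dz: 500nm
  overlap_fraction: 0.2
  autofocus_policy: jpeg
autofocus:
  method: jpeg
  range: 20um
seed: 1
output_dir: out
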