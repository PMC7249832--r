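Package: virtuscope
Title: Virtual Automated Microscopy: Autofocus, Optical Calibration and
    Tile Scanning on a Simulated Motorized Stage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic, seeded virtual microscope (three-axis stepper
    stage with backlash and drift, Gaussian-blur optics with vignetting and
    radial distortion, an 8-bit camera with shot and read noise and a real
    JPEG compressed-frame-size model) together with the automated-microscopy
    computations commonly run on such an instrument: Laplacian-filter
    sharpness autofocus, fast autofocus from the compressed size of frames
    in a video stream, knife-edge (edge-spread-function) estimation of the
    point spread function and its full width at half maximum, straight-edge
    radial distortion measurement, flat-field lens-shading calibration,
    pixel-size calibration from a periodic target, and autofocus-aware tile
    scans and time-lapses with z-stacks, phase-correlation stitching and
    central-crop compositing. Every analysis is exercised end-to-end against
    the simulator, so no hardware is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jpeg,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
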