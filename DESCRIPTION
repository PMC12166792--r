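Package: nanolock
Title: Image-Based Active 3D Sample Stabilization for Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Displacement estimation and feedback control for active,
    image-based 3D stabilization of a microscope sample stage. Lateral
    (x/y) displacements are estimated by cross-correlating a camera frame
    against reference stacks recorded at known stage positions; axial (z)
    displacement is read out from the mean squared error between sorted
    pixel-intensity profiles, exploiting the smooth change of the frame
    intensity distribution with defocus. A proportional-integral
    controller with a small second-order integrator term closes the loop.
    A virtual widefield microscope (holey carbon film, bead fields, tile
    targets, defocus, shot and read noise, stage drift) makes every stage
    of the pipeline testable without hardware, and analysis tools
    quantify stability, step response, staircase calibration, and drift
    reduction from loop logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
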