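Package: speckleflow
Title: Multi-Channel Speckle Contrast Optical Spectroscopy Analysis and
    Simulation
Version: 0.1.0
Authors@R:
    person("Speckleflow", "Developers", email = "speckleflow@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-distance speckle contrast optical
    spectroscopy (SCOS) recordings of scalp and cerebral hemodynamics:
    camera noise calibration from dark frames, noise-corrected speckle
    contrast, blood flow and blood volume indices, occlusion-segmented
    depth-sensitivity statistics, and beat-averaged cardiac waveform
    metrics.  Includes a seeded two-layer (scalp/brain) speckle-camera
    simulator with closed-form ground truth so every pipeline stage can
    be verified without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
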