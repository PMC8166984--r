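Package: negmar
Title: Metal Artifact Reduction for Parallel-Beam CT by Restricting Negative Pixels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces metal streak artifacts in parallel-beam x-ray computed
    tomography by estimating the metal-affected sinogram entries with
    gradient descent on an objective that penalizes only the negative
    pixels of the filtered-backprojection (FBP) reconstruction. Provides a
    matched forward-projector/backprojector pair, the exact band-limited
    ramp convolution kernel, metal segmentation and sinogram trace
    identification, the restricted subgradient-descent optimizer, a
    polychromatic (beam-hardening) phantom simulator, float-TIFF and YAML
    geometry I/O, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    tiff,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
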