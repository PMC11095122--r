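Package: slotsim
Title: Simulation and Digital Correction of Refraction Artifacts in Scanning
    Laser Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates scanning laser optical tomography (SLOT) acquisitions of
    two-dimensional digital phantoms under refractive-index mismatch between
    sample and immersion medium, using Snell's-law ray tracing at the sample
    boundary. Distorted sinograms are corrected by geometric rearrangement:
    each (angle, position) sample is moved to the (angle, position) at which an
    unrefracted ray would have acquired it. Includes filtered back projection
    for parallel-beam geometry, phantom generators (potato-shaped boundaries,
    logo-like structures, fluorescent-bead fields, resolution bars), and image
    quality metrics (SSIM and mean absolute pixel difference) over
    sample-derived regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
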