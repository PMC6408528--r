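Package: ionorange
Title: Ionoacoustic Range Verification with Resonant Gold Fiducial Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for proton-beam range verification from the
    thermoacoustic resonance of an implanted spherical gold fiducial marker.
    Provides an analytic Bethe/CSDA pencil-beam dose model on a voxel grid
    (with the marker hot spot and downstream cold shadow), Grueneisen
    conversion of deposited energy to an acoustic pressure source, a 3-D
    k-space pseudospectral wave solver with a perfectly matched layer, a fast
    spherically symmetric solver for the marker ringdown, spectral analysis of
    detector traces, the closed-form spherical-resonator theory (eigenmodes
    and pulse-width envelope), and a linear amplitude-to-residual-range
    calibration with error-budget utilities (transducer noise, tissue
    attenuation, spot-position sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
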