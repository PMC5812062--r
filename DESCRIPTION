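Package: holoshear
Title: In-Line Holographic Particle Imaging, Turbulence Diagnostics, and
    Jeffery-Orbit Orientation Statistics for Oceanic Shear Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for studying preferential
    particle orientation in stratified, weakly turbulent coastal waters.
    Provides synthetic in-line hologram generation for ground-truthed
    scenes of spheroidal and chain-forming particles, angular-spectrum
    numerical reconstruction with sub-window focus consolidation,
    particle segmentation and morphometry (equivalent diameter, aspect
    ratio, orientation, chain re-connection, overlap separation),
    depth-resolved concentration profiles, Junge-type particle size
    distribution slope fitting, orientation probability density maps,
    inertial-subrange dissipation-rate estimation from velocity spectra
    with Taylor's frozen-turbulence hypothesis, stratification
    diagnostics (buoyancy frequency, Richardson number), and the Jeffery
    orbit model of spheroid rotation in laminar shear used as the
    theoretical comparison for measured orientation distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
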