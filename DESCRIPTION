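Package: granmotion
Title: Single-Granule Motility Analysis by MSD Model Fitting and Motion
    Classification
Version: 0.1.0
Authors@R:
    person("Granule", "Motion Maintainers", email = "granmotion@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the intracellular motility of secretory
    vesicles (lytic granules) from single-particle tracking data. Computes
    per-track time-averaged mean square displacement (MSD) curves, fits
    random, directed and cage-confined diffusion models with a localization
    offset, sorts trajectories into five motion classes (immobile, random,
    directed, caged, complex) using fixed-cell-calibrated thresholds, and
    summarizes track geometry (length, displacement, straightness, speed)
    per experimental condition with histogram, cumulative-probability and
    class-fraction reporting. Includes a synthetic trajectory and movie
    generator (Brownian, drift plus diffusion, reflecting-cage and immobile
    regimes with Gaussian localization noise), Gaussian-spot rendering,
    detection by band-pass filtering and center-of-mass refinement, and
    nearest-neighbor linking with gap closing, so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
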