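Package: evlpp
Title: Single-Particle Analytics for Extracellular Vesicle and Lipoprotein Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-particle characterization of extracellular
    vesicles (EVs) and lipoprotein particles (LPPs) and their complexes:
    segmentation of optical-trapping Rayleigh/Raman time traces into
    trapping events with background-subtracted event spectra, principal
    component analysis of event spectra with chemical band annotation,
    spherical-cap morphometry of surface-adsorbed particles imaged by
    atomic force microscopy (contact angle and equivalent solution
    diameter), and calibrated fluorescence-triggered flow-cytometry
    quantification across density-gradient fractions (ERF/MESF
    calibration, time-based concentrations, spike-in and detergent-lysis
    comparisons). A ground-truthed synthetic-data generator emulates the
    relevant particle populations for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
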