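Package: mbdosim
Title: Synchrotron Microbeam Radiotherapy Dose Simulation and Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis chain for synchrotron microbeam
    irradiation dosimetry at a bending-magnet beamline. Synthesizes the
    filtered bending-magnet photon spectrum (Schwinger formula), ray-traces
    a tungsten multi-slit collimator for a divergent source, performs a
    simplified Monte Carlo photon transport (kerma approximation) with voxel
    dose scoring in a thin water layer, integrates virtual vertical scans,
    and analyses the resulting dose distributions for peak dose, valley dose
    and the peak-to-valley dose ratio (PVDR). Also provides radiochromic
    film dosimetry tools (net optical density, calibration fitting, dose-map
    conversion), seeded synthetic-data generators for film images and cell
    count tables, and survival-fraction statistics for irradiated versus
    control cell cultures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
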