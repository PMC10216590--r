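Package: omlitr
Title: Optical Multilayer Interference Simulation for Tape-Based Serial
    Section Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reflected-light contrast between stained cells and
    surrounding tissue in ultrathin resin sections collected on (optionally
    metal-coated) tape over a silicon wafer, the configuration used in optical
    multilayer interference tomography (OMLIT). Provides a transfer-matrix
    reflectance engine for arbitrary planar multilayers with incoherent thick
    layers, a material dispersion library, configuration sweeps that locate
    contrast optima over coating material, coating thickness, section thickness
    and LED wavelength, a seeded synthetic tissue phantom generator and section
    renderer with coating-defect artifacts, and ROI-pair image contrast
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
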