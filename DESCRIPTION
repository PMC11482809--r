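Package: filattice
Title: Helical Lattice Geometry, Decoration Occupancy, and Cooperative
    Binding Analysis for Actin Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the architecture of decorated actin
    filaments and the cooperativity of filament binding. Measures local
    helical lattice parameters (per-protomer twist and rise by screw-axis
    decomposition of inter-subunit rigid transforms), strand asymmetry and
    filament curvature on atomic filament models; generates synthetic
    filaments, decoration states and density volumes emulating
    conformational-variability map series; quantifies per-site bound-complex
    occupancy in density maps by zone segmentation and integrated intensity;
    and analyses dual-channel TIRF microscopy binding assays (rolling-ball
    background subtraction, Yen thresholding, mask conjunction, Hill-equation
    fitting of saturation binding curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
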