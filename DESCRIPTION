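Package: excitube
Title: Exciton Modelling of Double-Walled Tubular Dye Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cylindrical herringbone lattices of chromophores from a
    two-dimensional unit cell, rolls them into single- and double-walled
    nanotubes, and models their collective optical response with a Frenkel
    exciton Hamiltonian using extended-dipole couplings. Includes Gaussian
    diagonal (energetic) disorder and structural-jitter ensembles as a
    molecular-dynamics surrogate, readers for externally produced snapshots
    (PDB/GRO/XYZ), polarization- and wall-resolved absorption spectra,
    microelectrostatic solvent-shift calculations with point charges and
    self-consistent induced dipoles, and structural diagnostics such as
    pair angle-distance maps, coupling-sum histograms, and rolling-angle and
    packing-density scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
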