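Package: lamellaR
Title: Structural Analysis of Amyloid Aggregation in Oriented Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Membrane", "Biophysics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the structure of peptide aggregates in
    oriented lipid multibilayers from two-dimensional x-ray diffraction
    maps, scanning transmission x-ray microscopy (STXM) image stacks, and
    head-group coordinate surfaces.  Implements wedge and azimuthal
    integration of reciprocal-space maps, lamellar spacing and
    electron-density Fourier synthesis, chain-packing and cross-beta peak
    quantification with Scherrer domain sizing, lipid tilt and Hermans
    orientation analysis, Beer-Lambert optical-density conversion with
    two-component spectral unmixing and cluster morphometry, Monge-gauge
    membrane curvature, and a hydrophobic-mismatch line-tension free-energy
    model for cluster size.  A synthetic-data module generates every input
    class with known ground truth so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
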