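Package: memperm
Title: Membrane Permeation Energetics and Bilayer Structure from Particle Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for passive membrane permeation studies of small
    solutes in phospholipid bilayers. Computes mass, electron and number density
    profiles along the membrane normal with per-frame recentering; the standard
    bilayer structural estimators (area per lipid, headgroup peak-to-peak
    thickness, volume per lipid, deuterium order parameters) with block-averaged
    uncertainties; membrane/bulk partition coefficients from solute density
    profiles; potentials of mean force by inverse Boltzmann inversion with
    symmetrization, replica statistics and barrier/minimum feature extraction;
    and a didactic one-dimensional accelerated-weight-histogram adaptive-bias
    sampler on analytic potentials. Includes a synthetic hydrated-bilayer
    generator with known ground truth for validating every estimator, plus
    readers and writers for GRO/PDB coordinates and delimited profile tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
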