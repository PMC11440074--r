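Package: spherosim
Title: Image-Based Cellular Potts Simulation of Tumor Spheroids
Version: 0.1.0
Authors@R: person("spherosim", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for turning 3D single-cell label masks of multicellular
    spheroids into calibrated Cellular Potts Model (CPM) simulations.
    Provides a synthetic spheroid generator with controllable segmentation
    artifacts, label-mask cleanup (small-object removal, per-label
    closing/opening, thin-label merging, isotropic z-upsampling), per-cell
    3D morphometrics, CompuCell3D Potts Initial File (PIF)
    import/export, a Metropolis Monte Carlo CPM engine with per-cell
    volume and surface constraints and a frozen wall shell, and a
    calibration workflow that grid-scans contact energies and constraint
    weights, scoring runs by the product of mean Wasserstein distance over
    morphological feature distributions and mean per-cell intersection
    over union.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
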