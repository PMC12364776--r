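Package: starc
Title: Shoot-Through Static Proton Arc Planning and Range Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale treatment-planning toolkit for upright static proton
    arcs augmented with shoot-through (transmission) layers at the machine's
    maximum energy. Builds a fully specified virtual phantom on a voxel
    stopping-power-ratio grid, models a 5-230 MeV pencil-beam machine with
    analytic Bragg-Kleeman depth-dose and lateral-spread kernels, assembles
    static-arc and fixed-beam plans with per-layer collimation, optimizes spot
    weights against robust dose-volume and fall-off objectives with energy-layer
    and minimum-MU spot filtering, evaluates plans (Paddick conformity index,
    homogeneity index, worst-case robustness over 28 perturbation scenarios),
    estimates step-and-shoot delivery time from positioner and nozzle
    parameters, and simulates per-spot residual-range (relative
    water-equivalent-thickness) verification of the shoot-through protons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
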