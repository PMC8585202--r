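Package: dipscreen
Title: Dipole-Lattice Screening of Surfactant Translocation Across Lipid
    Bilayers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast screening of surfactant-membrane interactions with an
    implicit bilayer model. A lipid membrane is represented as a random
    lattice of point dipoles generated from per-lipid dipole statistics;
    a surfactant "agent" dipole is propagated through the resulting
    electrostatic field with a damped two-step Verlet integrator under a
    thermal kinetic-energy cap, and a Gibbs free-energy profile along the
    bilayer normal is accumulated from Hamiltonian differences plus a
    logP-derived octanol-water transfer enthalpy applied at the
    water/membrane boundary. Includes profile feature extraction
    (translocation free energy, interface barriers, membrane minima),
    replicate statistics over membrane realisations, plain-text readers
    and writers for parameter files, membranes, trajectories and energy
    profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
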