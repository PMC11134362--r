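Package: regucharge
Title: Constant-pH Simulation of Charge Regulation and Oligocation
    Condensation on Polyelectrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained bead-spring model of short weak-base oligocations
    (oligolysines) interacting with a long, fully ionized polyanion in implicit
    solvent.  Protonation states are sampled by constant-pH Monte Carlo coupled
    to Langevin dynamics, with Debye-Hueckel implicit-ion electrostatics (an
    explicit-ion truncated-Coulomb mode is provided for cross-checks).  The
    package computes titration curves, effective pKa shifts, distance-resolved
    ionization, condensed fractions and polyanion end-to-end distances;
    provides analytic mean-field formulas, Manning-condensation helpers and an
    exact enumeration oracle for validation; generates synthetic two-population
    trajectory fixtures; and drives reproducible pH sweeps with extended-XYZ
    trajectory I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
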