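Package: amdenm
Title: Adaptive Molecular Dynamics with Excited Normal Modes on Coarse-Grained Bead Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of adaptive molecular dynamics with
    excited normal modes (aMDeNM): elastic-network normal-mode analysis,
    randomized mode-combination excitation directions with a structure-diversity
    filter, kinetic-energy injection in short Langevin segments with adaptive
    direction updates, and downstream conformational-landscape analyses
    (RMSF/RMSD, inertia-anchored center-of-mass tracking, residue-pair
    nonbonded interaction-energy maps).  Includes a synthetic two-domain
    bead-model generator (a compact globular domain plus a flexible tail
    ending in a helix) so the full pipeline is testable without external
    structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
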