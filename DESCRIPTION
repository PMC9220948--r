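Package: raftsizer
Title: Line-Tension and Dipole Energetics of Lipid Raft Domain Size
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuum energy model for the equilibrium size of liquid-ordered
    (raft) domains in a lipid bilayer. The total energy of a population of
    circular domains covering a fixed membrane area is the sum of a boundary
    (line-tension) term, which favours few large domains, and an electrostatic
    term from the permanent lipid dipoles of the two leaflets, which favours
    many small ones. The package evaluates both terms via quadrature against
    the pair-distance distribution of a disk, minimises the total energy over
    domain radius, sweeps line tension to expose the exponential size-growth
    law, inverts the size-tension map to infer line tension from an observed
    domain radius, and provides seeded synthetic-data generators (noisy domain
    radii; affinity versus phospho-readout datasets) with the matching
    parameter-recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
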