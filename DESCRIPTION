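Package: glycofit
Title: Re-Optimization of Carbohydrate Force-Field Torsions and Charges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for re-fitting AMBER/GLYCAM-style force-field parameters
    of beta-d-glucose against reference conformer energies. Provides a
    vacuum molecular-mechanics energy engine with the standard AMBER
    functional form, curation of conformer datasets (duplicate removal by
    RMSD, Lennard-Jones outlier filtering, train/test splitting, per-atom
    charge statistics), penalized least-squares fitting of torsion Fourier
    coefficients, atomic charges and the 1-4 electrostatic scaling factor
    by Adadelta gradient descent, an improvement decomposition comparing
    two parameter sets, conformational deformation scans (bond rotations,
    ring flip, Cremer-Pople puckering, hydroxymethyl rotamer analysis),
    and a synthetic conformer generator with a ground-truth energy oracle
    so the whole pipeline is testable without quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
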