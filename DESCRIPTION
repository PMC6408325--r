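Package: bendkit
Title: Conformational and Thermodynamic Analysis of Tubulin-Binder Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural characterization of alpha-beta tubulin
    heterodimers in complex with small protein binders (artificial repeat
    proteins, DARPins, stathmin-like domains and the like). Implements
    rigid-body Kabsch superposition with rotation-angle extraction, the
    inter-subunit tubulin bend (curvature) angle measured by superposing the
    secondary-structure elements of the alpha N-terminal domain onto the
    equivalent beta elements, intra-subunit metrics (H7 helix shift, pairwise
    complex RMSD), Shrake-Rupley solvent-accessible surface areas, buried
    interface areas, residue-residue contact and steric-clash mapping
    (including grafting a complex onto a protofilament lattice), and one-site
    binding thermodynamics: the closed-form 1:1 sequestration equilibrium and
    simulation plus nonlinear least-squares fitting of isothermal titration
    calorimetry isotherms. A synthetic-structure and synthetic-isotherm
    generator with known ground truth makes every stage testable without
    downloading coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
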