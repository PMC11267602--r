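Package: csmeasure
Title: Continuous Symmetry and Chirality Measures for Molecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the distance of a molecular geometry from its nearest
    structure possessing a given cyclic point-group symmetry (Cs, Ci, Cn, Sn),
    on a continuous 0-100 scale (the continuous symmetry measure, CSM), and
    the related continuous chirality measure (CCM) as the minimum over all
    achiral cyclic groups.  Provides exact permutation-enumeration search
    (optionally restricted to bond-graph automorphisms), an approximate
    direction-permutation algorithm for large molecules built on Hungarian
    assignment and Fibonacci-sphere axis seeding, and a chain-permutation
    search for protein homo-oligomers.  Reads and writes xyz, pdb, mol/sdf
    (V2000) and an internal csm dialect, infers covalent connectivity, and
    ships a deterministic generator of exactly symmetric and perturbed test
    geometries plus a command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
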