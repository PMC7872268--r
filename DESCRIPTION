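Package: homodel
Title: Homology Modelling Toolbox with Fragment-Based Loop Building and
    Rotamer-Graph Sidechain Packing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scriptable homology-modelling engine for single-chain protein
    targets. Provides a peptide backbone container with synchronised Cartesian
    and internal (torsion) coordinates, cyclic coordinate descent loop closure,
    a linear structural database with a stem-geometry-hashed fragment index,
    knowledge-based statistical potentials trained by inverse Boltzmann
    statistics, combinatorial sidechain packing on rotamer graphs (dead-end
    elimination, edge decomposition, exact tree-decomposition dynamic
    programming, A* enumeration and Monte Carlo sampling), and an end-to-end
    model building pipeline from a target-template alignment, including a
    command line interface. All test inputs are generated synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
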