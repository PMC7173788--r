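Package: mdflow
Title: Dataflow-Graph Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A typed dataflow-graph engine for analysing molecular dynamics
    trajectories. Analysis algorithms are expressed as graphs of nodes with
    typed ports; a mutable per-atom attribute store carries state between
    frames, enabling recurrent algorithms that can be executed forward or
    backward in time. Ships node packs for nucleated-cluster identification
    and tracking in particle systems (neighbour lists, connected components,
    largest-cluster masks, recurrent cluster tracking, colour graduation) and
    for clathrate-hydrate recognition via the mutually coordinated guest
    (MCG-1) order parameter (guest pairing, coordinated-water cones, geometric
    hydrogen bonds, oxygen-network ring perception). Includes readers for
    GRO, PDB, LAMMPS text dump and a generic space-separated attribute format,
    comment-annotated script nodes, exportable visualization state, synthetic
    fixture generators with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
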