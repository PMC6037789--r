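Package: aggscape
Title: Aggregation Topology and Free-Energy Landscapes of Peptide
    Self-Assembly Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of short amyloid-peptide self-assembly trajectories:
    geometric backbone hydrogen-bond detection, hydrogen-bond-pattern
    secondary-structure assignment, graph-based identification of oligomers,
    beta-sheets, beta-sheet oligomers and closed beta-barrels, mass-weighted
    size statistics, strand-alignment and residue contact-frequency analysis,
    and two-dimensional potential-of-mean-force landscapes over oligomer size
    and per-chain beta content.  Includes a deterministic generator of
    synthetic conformations (coils, helices, single- and double-layer
    beta-sheets, beta-barrels) with ground-truth labels, simulation
    bookkeeping arithmetic (concentration, discrete-molecular-dynamics time
    units, Debye screening), and multi-model PDB plus plain-text trajectory
    input/output.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
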