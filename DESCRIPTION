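Package: quasidock
Title: Quantum Quasi-Docking of Flexible Ligands in Rigid Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-step quasi-docking of a flexible ligand in a rigid receptor:
    a multi-start stochastic search enumerates the unique low-energy minima of
    the protein-ligand complex under a fast force-field-style energy model
    (random rigid-body placement and torsion randomization, clash rejection,
    L-BFGS local optimization over all ligand Cartesian coordinates, and a
    fixed-capacity pool of RMSD-deduplicated minima), after which every pool
    minimum is re-scored single-point by a slower energy model (an external
    semiempirical quantum-chemistry program via a MOPAC-dialect file
    interface, or a bundled smooth surrogate) and re-ranked. Positioning
    accuracy is evaluated with heavy-atom and symmetry-corrected RMSD and the
    Index Near Native (INN), and protein-ligand binding enthalpy is estimated
    from global-minimum energies of the complex, the unbound protein, and the
    unbound ligand. Desk-scale synthetic complexes with enumerable minima
    landscapes and packaged benchmark tables support end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    ChemmineR,
    optparse,
    withr
Config/testthat/edition: 3
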