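Package: dockminima
Title: Exhaustive Low-Energy Minima Search and Multiwell Binding Free
    Energies for Rigid-Receptor Flexible-Ligand Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the exhaustive enumeration of low-energy local
    minima of a rigid-receptor/flexible-ligand system by Monte Carlo pose
    sampling with local gradient minimization, and for evaluating docking
    target functions through the resulting minima spectra.  Maintains a
    capacity-bounded, RMSD-deduplicated minima set; computes near-native
    pose indices (IN/INN), RMSD profiles and single-linkage pose clusters;
    estimates protein-ligand binding free energies in the multiwell
    (mining-minima style) harmonic approximation from Hessian normal
    modes and rigid-rotor/ideal-gas partition functions; and reproduces
    energy-range and correlation summaries over benchmark complex sets.
    A deterministic synthetic-system generator with analytically known
    minima supports testing without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    tools
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
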