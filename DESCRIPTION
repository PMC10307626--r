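Package: ninjfil
Title: NINJ1 Filament Assembly, Coupling Mapping and Membrane-Rupture Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analyses behind the NINJ1 filament
    mechanism of plasma membrane rupture. Builds linear filaments, closed
    rings and antiparallel double filaments from a protomer and a screw
    symmetry (rise per subunit in Angstrom, signed twist in degrees) and
    estimates screw parameters from coordinates by least-squares
    superposition; classifies evolutionary-coupling residue pairs as intra-
    versus inter-protomer contacts on an assembly; quantifies amphipathic
    face segregation, hydrophobic belt height and helix hydrophobic moments;
    clusters single-molecule localizations (DBSCAN) and computes cluster
    morphometrics (radius of gyration, eccentricity) with per-experiment
    median comparisons; and implements the membrane-assay normalizations
    (percent-of-controls lysis and uptake, dithionite-quench permeability,
    dye release, DRAQ7 onset, inhomogeneity baselining). Synthetic-data
    generators provide protomers, localization fields, coupling tables and
    assay traces with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
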