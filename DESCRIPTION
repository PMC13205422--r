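Package: gelmesh
Title: Mesh Sieving and Affinity Analysis of Cross-Linked Nanogel Drug Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds explicitly cross-linked P(NIPAM-co-AAc)/BIS polymer
    network topologies by an iterative distance-plus-template reaction
    scheme, characterizes their periodic pore structure (pore limiting
    diameter and maximum pore diameter) by grid distance transforms with
    Hoshen-Kopelman percolation labeling, computes trajectory statistics
    for an embedded drug (Einstein-relation diffusion coefficients from
    mean-squared displacements, dissociated fractions from average
    minimum-distance criteria, geometric hydrogen-bond counts, radial
    number density profiles), and analyses drug-release measurements
    (cumulative release, zero-order/first-order/Higuchi/Korsmeyer-Peppas
    kinetic fits with transport-mechanism classification, release AUC,
    within-material centering, and Spearman rank correlation of
    simulation descriptors with release). Ships seeded synthetic-data
    generators with analytic ground truth for every input class so the
    whole pipeline is testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
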