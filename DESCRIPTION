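Package: spinemorph
Title: 3D Morphometry and Synaptic Connectivity of Dendritic Spines from
    Volume Electron Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of labeled dendrites,
    dendritic spines, synaptic junctions and presynaptic boutons in
    anisotropic volume electron microscopy (FIB/SEM) image stacks.
    Provides translation-only slice alignment, across-slice intensity
    normalization, seeded region growing on a blurred companion stack,
    spine isolation from the parent shaft, voxel- and mesh-based
    measurement of volume, surface area and Wadell sphericity,
    morphological spine typing (thin, filopodial, stubby, mushroom,
    branched), spine-synapse-bouton connectivity with the synaptic
    bouton index (SBi), and a binned two-regime breakpoint regression.
    A parametric phantom generator renders synthetic stacks with exact
    ground truth so every stage can be validated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
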