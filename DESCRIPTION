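Package: pammotif
Title: Data-Driven Recognition of Atomic Motifs in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised recognition of atomic-scale motifs in protein
    crystal structures. Implements probabilistic analysis of molecular
    motifs (PAMM): farthest-point sampling of a sparse grid, adaptive
    kernel density estimation with periodic-variable support, quick-shift
    mode seeking and Gaussian-mixture construction, yielding probabilistic
    motif identifiers (PMIs) for hydrogen-bond geometries and backbone
    dihedral conformations. Includes heuristic distance-angle and
    Kabsch-Sander (DSSP energy) hydrogen-bond definitions with a
    normalized agreement score between definitions, joint-probability
    benchmarking of clusters against DSSP/STRIDE secondary-structure
    labels (Q3/Q8 accuracy), SOAP power-spectrum descriptors of backbone
    environments with FPS component selection and PCA reduction, a
    supervised SVM baseline, and seeded synthetic-structure generators so
    the whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
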