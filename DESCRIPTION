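Package: allopath
Title: Allosteric Signature Analysis of GPCR Trajectory Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Detects positive-allosteric-modulation signatures in simulated
    G-protein-coupled receptor complexes by comparing two simulated
    conditions: bootstrap residue contact-frequency estimation, weighted
    residue-interaction networks with eigenvector centrality, three-state
    secondary-structure assignment from the Kabsch-Sander backbone
    hydrogen-bond energy, ligand RMSD in evolution and pairwise schemes,
    center-of-mass distances between transmembrane subsegments, and
    receptor/G-alpha interface contact difference maps.  Ships a synthetic
    trajectory generator that plants parameterized helicity, contact and
    interface effects so every analysis stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
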