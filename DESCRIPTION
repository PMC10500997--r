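Package: sugres
Title: Coarse-Grained SUGRES-1P Simulations of Heparin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for unbound heparin chains in the SUGRES-1P
    coarse-grained representation: one anisotropic head/tail interaction
    site per sugar residue on a virtual-bond chain anchored at the
    glycosidic oxygens.  Implements the weighted effective energy function
    (Gay-Berne tail-tail interactions, generalized Born polarization,
    cavity terms, Lennard-Jones head contacts and Debye-Hueckel screened
    electrostatics) with analytic forces, canonical Langevin dynamics,
    a weight/kappa calibration sweep scored against experimental
    end-to-end distances and radii of gyration, and trajectory analysis
    (end-to-end distance, radius of gyration, anchor RMSD, DBSCAN
    conformational clustering).  Includes idealized helical template
    generators so every computation runs from synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
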