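Package: AbAgDock
Title: Flexible-Paratope Monte Carlo Docking of Antibody-Antigen Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-body Monte Carlo docking for antibody Fv fragments and their
    antigens. The protocol simultaneously optimizes the antibody-antigen
    rigid-body placement, the relative orientation of the light and heavy
    variable domains, and the backbones of the six complementarity determining
    region (CDR) loops, using fold-tree kinematics, cyclic coordinate descent
    loop closure, a two-resolution (centroid/full-atom) representation, and
    Metropolis Monte Carlo acceptance. Includes the standard docking-quality
    evaluation stack (ligand rmsd, interface rmsd, fraction of native contacts,
    CAPRI-style ratings, energy-funnel detection), ensemble conformer-selection
    docking, and programmatic generators of toy antibody-like complexes for
    desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
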