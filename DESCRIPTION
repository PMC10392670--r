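Package: dnatwist
Title: Torsional Mechanics of DNA from Twist-Restrained Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the torsional elasticity of double-stranded
    DNA probed by end-to-end-twist restrained umbrella sampling. Provides
    rigid-base-pair helical parameter geometry (base and base-pair reference
    frames, the six inter- and six intra-base-pair parameters, axis bending,
    groove geometry, Watson-Crick hydrogen-bond integrity), a quadratic
    end-to-end-twist restraint, a Gaussian-mixture rigid-base-pair Monte
    Carlo generator with bimodal twist-capacitor steps, the weighted
    histogram analysis method (WHAM) for twisting potentials of mean force,
    torsional force constants and moduli via the homogeneous rod model,
    supercoiling-density conversion, a harmonic multi-substate deformation
    energy evaluator with nearest-neighbour Ising coupling, and protein-DNA
    contact classification with per-frame occupancies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
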