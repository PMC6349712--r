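Package: ecginverse
Title: Activation and Repolarization Mapping by Parameter Identification
    from Body-Surface Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Noninvasive electrocardiographic imaging (ECGI) by parameter
    identification. Each heart-surface node carries an action-potential
    ansatz built from the two-variable Mitchell-Schaeffer ionic model,
    shifted by a per-node activation time and rescaled by a global
    amplitude. Transmembrane voltages are mapped to extracellular
    potentials by spatial-mean referencing and projected to body-surface
    electrodes through an infinite homogeneous medium kernel. The inverse
    problem recovers the distributed activation times and repolarization
    parameters (tau_out, tau_close) by RMSprop gradient descent on a
    mean-centered least-squares cost with an analytically computed
    gradient. Includes triangulated surface-mesh I/O and geodesics,
    synthetic validation scenarios (pacing-driven activation, distributed
    parameter fields, noise and model-mismatch modes), and the evaluation
    metrics used in ECGI validation (correlation, relative error, BSPM
    fit, endo-epicardial delays, pacing-site localization, APD90).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
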