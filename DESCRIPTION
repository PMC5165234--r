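Package: gcsim
Title: Agent-Based Germinal Center Simulation with Virtual Two-Photon Read-Outs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lattice-based agent simulation of germinal center (GC) reactions:
    persistent random walk of B and T follicular helper cells with hysteretic
    transient chemotaxis on precomputed CXCL12/CXCL13 fields, two-step light-zone
    selection (antigen collection on follicular dendritic cells, then T cell
    help), a Hill-function dynamic number of divisions, asymmetric antigen
    inheritance, antibody feedback masking free antigen, and continuous founder
    influx. Includes in-silico two-photon measurement procedures: displacement
    curves and motility coefficients, speed and turning-angle distributions,
    photoactivation transzone tracking, dark-zone to light-zone ratios, and the
    targeted antigen-delivery (anti-DEC205) experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
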