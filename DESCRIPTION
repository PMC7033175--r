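Package: impedCyto
Title: Multi-Frequency Impedance Cytometry Simulation and Event Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multi-frequency microfluidic impedance cytometry of
    immuno-magnetically separated samples. Provides an equivalent-circuit
    forward model of a coplanar two-electrode sensor (double-layer
    capacitance, solution resistance, and a particle branch with occlusion
    resistance, membrane capacitance and cytoplasm resistance), a seeded
    generator of multi-frequency lock-in traces with ground-truth event
    logs, a wavelet (MODWT) baseline-drift removal and denoising chain with
    Coulter-type pulse detection and per-frequency amplitude/SNR
    quantification, and gating utilities (Gaussian-mixture amplitude fits,
    two-frequency SNR covariance ellipses, amplitude thresholding) that
    separate bare magnetic beads, cells and bead-cell aggregates and count
    aggregates as the surface-marker readout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    mclust,
    pracma,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: FlowCytometry, SingleCell, Software
RoxygenNote: 7.3.3
LinkingTo: Rcpp
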