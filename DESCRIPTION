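Package: laminarLFP
Title: Independent-Component Analysis of Laminar Motor-Cortex Field
    Potentials and Reservoir Modelling of Task-Related Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes multi-channel laminar local field potentials (LFPs)
    into depth-specific independent components (PCA reduction followed by
    ICA), and characterizes the components by their spatial voltage and
    current-source-density loadings, a Sobolev-type loading dissimilarity
    with hierarchical clustering across animals, Morlet-wavelet and Welch
    spectra, theta-gamma phase-amplitude coupling (Tort modulation index
    with trial-shuffling surrogates), and spike-field phase locking
    (Rayleigh test, phase-locking value, Watson-Williams comparisons).
    The components can drive a rate-based recurrent reservoir network
    whose readout is trained with FORCE (recursive least squares) to
    reproduce a lever trajectory, after which reservoir neurons are
    classified into functional subtypes (hold-related/movement-off,
    movement-related, pre-movement, post-movement) and sorted by circular
    activation time. A synthetic-data generator emulates laminar
    recordings with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
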