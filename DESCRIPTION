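Package: synaptomap
Title: Functional Synaptic Connectivity Mapping from Single-Cell
    Optogenetic Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring functional synaptic connectivity from
    sequential single-cell optogenetic stimulation during whole-cell
    voltage-clamp recording. Implements template-deconvolution detection
    and multi-event decomposition of excitatory postsynaptic currents
    (EPSCs), Bayesian connected/not-connected classification of stimulated
    cells by Hamiltonian Monte Carlo model comparison (PSIS-LOO with
    Bayesian-bootstrap pseudo-BMA weights), connection-strength
    estimation, photocurrent artifact subtraction, intrinsic
    electrophysiology feature extraction, robust ZCA whitening with
    Horseshoe-prior sparse logistic regression for connectivity
    determinants, and map-level geometric summaries. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
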