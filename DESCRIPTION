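Package: vfmemory
Title: Vertical Visual-Field Effects on Item and Spatial Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for source-monitoring experiments in which
    objects are encoded in the upper or lower visual field and memory for the
    item (old/new) and its vertical position (up/down) is tested. Implements
    Pr discrimination indices, the dual-process source-item multinomial
    processing tree (MPT) model with maximum-likelihood and latent-trait
    hierarchical Bayesian estimation (Metropolis-within-Gibbs, split R-hat
    diagnostics, posterior predictive checks, posterior group differences),
    kinetic-perimetry hemifield areas with the vertical meridian asymmetry
    (VMA) index, velocity-based fixation detection with Fujii 2/4 stability
    grading for eye-tracking quality control, and ground-truth synthetic data
    generators for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
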