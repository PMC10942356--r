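Package: ephate
Title: Multi-View Manifold Learning with Exogenous PHATE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements exogenous PHATE (E-PHATE), a multi-view nonlinear
    manifold-learning method that fuses a diffusion operator built from
    high-dimensional per-subject measurements (for example voxel-wise fMRI
    activation) with an affinity operator built from low-dimensional exogenous
    covariates (for example family and neighborhood environment scores), and
    embeds the fused operator with metric multidimensional scaling. Includes
    the underlying alpha-decay adaptive kernel and diffusion-operator
    machinery, von Neumann entropy time-scale selection, potential distances,
    SMACOF stress majorization, cross-validated linear prediction scored by
    partial Spearman correlation with paired sign-flip permutation tests, a
    log-linear corrected d-prime, and a synthetic-data generator that plants a
    latent brain manifold, a correlated environment view, and
    interaction-driven outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
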