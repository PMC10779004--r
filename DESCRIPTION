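Package: nmmdfit
Title: Normal-Mode Molecular Dynamics Flexible Fitting of Cryo-EM
    Particles and Conformational Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-particle flexible fitting of an atomic model to cryo-EM
    single-particle images or subtomograms using normal-mode-accelerated
    molecular dynamics (NMMD) with a coarse-grained Ca Go force field and a
    normalized cross-correlation biasing potential, followed by construction
    and analysis of continuous conformational landscapes: ensemble
    superposition, PCA/UMAP embedding, free-energy maps, clustering,
    trajectories along landscape axes and per-cluster density averages.
    Includes a synthetic-data generator (toy structures deformed along
    elastic-network normal modes, rendered to noisy images or volumes at
    known poses) so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ggplot2,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
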