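Package: tdcsim
Title: Electric-Field Simulation and Electrode-Placement Optimization for
    Transcranial Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Finite-element simulation of transcranial direct current
    stimulation (tDCS) induced electric fields in labeled tetrahedral head
    models, with skin-surface grid-search optimization of bi-hemispheric
    electrode montages toward a hand-motor target. Builds synthetic
    multi-layer spherical head models with stroke lesions, locates 10-20
    scalp positions from fiducials, solves the piecewise-conductivity
    Laplace problem with a conjugate-gradient (or sparse Cholesky) solver,
    validates against the analytic multi-layer sphere series, and compares
    optimized against conventional C3/C4 montages with region-of-interest
    field summaries, montage-distance metrics and nonparametric cohort
    statistics on a synthetic stroke cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
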