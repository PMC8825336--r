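Package: cellplate
Title: Variational Energetics of Plant Cell Plate Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuum-mechanics model of the membrane transitions that turn a
    plant cytokinetic vesicle network into a mature cell plate. Conformations
    are assembled from oblate spheroids (vesicles, late-stage plates) joined by
    elliptic hyperboloid tubes with fenestrations counted as surface genus, and
    their free energy is a modified Helfrich functional with bending,
    osmotic-pressure, tension, Gaussian (topological) and two-dimensional
    spreading-force terms. The energy is minimized over the shared shape
    parameters at fixed total membrane area, giving stability curves of
    tubular and fenestrated networks against the single oblate spheroid,
    equilibrium thickness sweeps, spontaneous-curvature thresholds, and
    spreading-force parameter maps. Companion physiological calculations
    include van't Hoff osmotic concentrations and a two-dimensional Flory
    polymer model linking polysaccharide synthesis rates to the spreading
    force. Triangulated-mesh estimators (angle-defect Gaussian curvature,
    cotangent-Laplacian bending) provide independent verification of all
    quadrature results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
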