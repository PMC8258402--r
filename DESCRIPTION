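Package: lsamorph
Title: Morphometry of Lenticulostriate Arteries from Vessel Delineations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for quantifying the morphology of
    lenticulostriate arteries (LSAs) from binary vessel delineations.
    Turns 2D (or thin-slab projected 3D) masks into single ordered
    centerlines via skeletonization, spur pruning and longest-geodesic
    path extraction, computes per-vessel tortuosity metrics (vessel
    length, distance metric, and the composite vessel tortuosity index
    with its angle, critical-point and curvature-magnitude
    subcomponents), summarizes them per subject, and runs
    covariate-adjusted cohort statistics (ANCOVA-style group
    comparisons, partial Spearman correlations, chi-square tests,
    Bonferroni correction, intraclass correlation). Includes a
    synthetic-data module generating analytic ground-truth curves,
    rasterized vessel phantoms and simulated cohorts so every stage is
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    MASS,
    RNifti,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
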