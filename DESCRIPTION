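Package: LesionTopo
Title: Lesion Topography Analysis of Rehabilitation Outcome After Stroke
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating stroke lesion topography to rehabilitation
    outcome. Implements weighted corticospinal-tract lesion load (wCST-LL)
    scoring of binary lesion masks against a canonical tract, covariate-adjusted
    voxel-based lesion-symptom mapping (VLSM) with max-statistic permutation
    family-wise error correction, atlas-based cluster labelling, and the
    accompanying behavioural statistics battery (Kendall correlations, Wilcoxon
    effect sizes, multiple and proportional-odds ordinal regression). A seeded
    synthetic lesion-cohort generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LesionTopo-package.R'
    'volume-grid.R'
    'volumes-io.R'
    'vlsm.R'
    'atlas-report.R'
    'behaviour-stats.R'
    'tract-load.R'
    'synthetic-cohort.R'
    'pipeline.R'
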