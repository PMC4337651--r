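Package: sectorFISH
Title: Colony-Sector and Single-Molecule RNA FISH Statistics for
    Heterochromatic Silencing-Loss Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies rare, transient losses of heterochromatic gene
    silencing that are captured as permanent fluorescent-reporter switches.
    Provides a branching-process simulator of colony growth with irreversible
    per-division switching (including a cell-cycle-resolved timing mode), the
    half-sector frequency estimator with replicate summaries, fold-changes,
    Student's t tests and bootstrap confidence intervals, a synthetic
    single-molecule RNA FISH generator (per-cell transcript counts and
    anisotropic 3D image stacks with ground truth), a 3D
    Laplacian-of-Gaussian spot caller with per-cell count summaries, and an
    idealized plate renderer with a threshold-based colony counter.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'rng.R'
    'colony-model.R'
    'sector-stats.R'
    'count-models.R'
    'fish-synth.R'
    'labeling.R'
    'spot-caller.R'
    'plate-imaging.R'
    'io.R'
    'config.R'
    'experiments.R'
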