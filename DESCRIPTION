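Package: vascter
Title: Probabilistic Arterial Territory Atlases from Stroke Lesion Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds probabilistic and sharp (hard-label) atlases of brain
    arterial territories from cohorts of binary stroke-lesion masks in a
    common template space. Implements the voxelwise average (lesion
    frequency) method and a Bernoulli mixture model fitted by
    expectation-maximization, with cluster-count selection by a minimum
    cluster-fraction rule. Turns probability maps into territory-claimed
    voxel maps via a confidence rule, resolves multi-territory overlaps,
    labels unclaimed voxels by nearest-territory water-spreading, and emits
    hierarchical label volumes with lookup tables. Includes border-zone
    probability-ratio maps, voxelwise certainty indices with per-ROI
    summaries, strip-region registration quality metrics, and a synthetic
    phantom cohort generator with planted mixture structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
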