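Package: restiba
Title: Resting-State Intrinsic Brain Activity Metrics with Synthetic BOLD Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-to-whole-brain analysis of resting-state fMRI intrinsic brain
    activity. Implements the temporal preprocessing chain (initial volume discard,
    linear detrending, Friston-24 plus white-matter/cerebrospinal-fluid nuisance
    regression, ideal band-pass filtering, framewise displacement and motion
    quality control), five activity metrics (ALFF, fALFF, PerAF, regional
    homogeneity via Kendall's coefficient of concordance, and degree centrality),
    global-mean standardization and Gaussian smoothing, voxelwise two-sample
    group inference with Gaussian-random-field cluster-level correction, and
    behavioral partial correlations with false-discovery-rate control. A seeded
    synthetic two-group BOLD cohort generator with planted amplitude, synchrony
    and hub effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
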