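Package: connectoscope
Title: Resting-State fMRI Connectome Analysis with Graph Topology and
    Multi-Kernel SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven pipeline for resting-state functional MRI group
    studies: synthetic two-group BOLD cohort generation with planted amplitude,
    coherence and connectivity effects; time-series cleaning (volume trimming,
    motion quality control, linear detrending, ideal bandpass filtering,
    nuisance regression); voxelwise ALFF, fALFF and ReHo maps with Gaussian
    smoothing and standardization; 90-node Pearson connectomes thresholded
    over a sparsity grid; global and nodal graph-topology metrics normalized
    against degree-preserving null networks and summarized as area under the
    sparsity curve; covariate-adjusted group statistics with permutation-based
    cluster correction and false-discovery-rate control; and multi-kernel
    support-vector-machine classification with nested leave-one-out
    cross-validation and consensus-connection extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    kernlab,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
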