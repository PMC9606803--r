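Package: assomap
Title: Voxel-Level Association Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voxel-level association (Asso) mapping of resting-state
    fMRI. The association index of a voxel counts the pairs of its
    supra-threshold functional neighbors that are not directly interconnected,
    so that, unlike plain degree centrality, it credits a voxel for mediating
    between otherwise weakly coupled regions. The package provides NIfTI and
    tabular I/O, temporal preprocessing (volume dropping, detrending,
    band-pass filtering, Friston-24 plus tissue nuisance regression, and
    framewise-displacement scrubbing with linear interpolation), Asso and
    degree-centrality maps, seed-based functional connectivity with Fisher z,
    covariate-adjusted voxelwise group inference with permutation cluster
    correction, linear-SVM leave-one-out biomarker evaluation, brain-behavior
    correlations with false-discovery-rate control, and a synthetic two-group
    cohort generator with planted, recoverable effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
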