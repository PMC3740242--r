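Package: v1decode
Title: Simulation and Multivoxel Decoding of Orientation Representations in V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual orientation is encoded in functional
    MRI response patterns of primary visual cortex (V1). The package constructs
    log-polar orientation stimuli (uniform gratings, logarithmic spirals, and
    patch-swapped variants that destroy global form while preserving local
    orientation disparity), simulates voxelized V1 cohorts with columnar-scale
    and global (radial/vertical) orientation-preference structure, estimates
    subrun-wise t-value activity patterns with a Boynton-style hemodynamic
    general linear model, decodes stimulus orientation with a linear support
    vector machine under leave-one-subrun-out cross-validation, resolves the
    spatial scale of pattern information with ROI-masked Gaussian low-, high-
    and band-pass filtering, infers radial and vertical preference maps from
    patch-level response tables via cosine tuning models and rank-order tests,
    and quantifies the impact of head motion on decodability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    RNifti,
    png
Config/testthat/edition: 3
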