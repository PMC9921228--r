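Package: jcmica
Title: Joint Connectivity-Matrix Independent Component Analysis for
    Multimodal Brain Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes functional connectivity (voxel-wise temporal
    correlation, never formed explicitly) and structural connectivity
    (tractography fiber-count matrices) into shared gray-matter spatial
    sources and, per modality, their connectivity maps (functional networks
    and white-matter tracts). Implements the single-subject SVD shortcut for
    connectivity-matrix ICA, two-stage group PCA with balanced modality
    concatenation, Infomax/fastICA unmixing with ICASSO-style stability
    selection, GICA back-reconstruction of subject maps, a contribution-ratio
    screen for shared sources, threshold-based region extraction, and
    atlas-overlap labeling. Includes a synthetic multimodal cohort generator
    with known ground truth for validation, NIfTI/MatrixMarket I/O, and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
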