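Package: fastkurt
Title: Fast Diffusion Kurtosis (1-9-9) Estimation, Lesion Volumetry and
    Cavalieri Stereology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-form estimation of mean diffusivity (MD) and the mean of
    the kurtosis tensor (MKT) from the 19-image 1-9-9 fast diffusion kurtosis
    protocol (one b = 0 volume plus nine directions at each of two shells),
    voxelwise parametric map fitting with quality flags, threshold-based
    stroke lesion segmentation and mask volumetry, Cavalieri stereological
    volume estimation from systematically sampled sections (point counting
    and 2D nucleator area estimators), and the associated statistical
    comparisons (Shapiro-Wilk, paired t, one-way ANOVA, two-way
    absolute-agreement ICC). Includes a synthetic two-hemisphere stroke
    phantom with nested MD/MKT lesions and Rician noise simulation so every
    stage of the pipeline can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
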