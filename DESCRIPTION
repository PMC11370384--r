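Package: hippomicro
Title: Surface-Based Modelling of Hippocampal Microstructure Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward biophysical diffusion-MRI signal models (diffusion
    tensor, NODDI Watson-dispersed sticks, SANDI soma-and-neurite spherical
    means) and their estimators; Laplace-equation coordinate fields over the
    hippocampal gray matter with gradient-based orientation (cosine
    similarity) maps; midthickness surface construction, sampling,
    subfield and long-axis parcellation; and the developmental statistical
    battery (tiered Pearson screening, nested-model F-tests with FDR,
    vertex-wise age contrasts, positional-gradient correlation, and a
    spin-test permutation scheme on the unfolded surface). A synthetic-data
    generator produces cohorts, multi-shell protocols, ground-truth
    parameter surfaces with configurable age and sex effects, Rician-noise
    signal volumes, and an analytic curved-slab phantom, so the whole
    pipeline runs and is testable end-to-end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
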