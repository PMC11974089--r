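Package: alpsdti
Title: DTI-ALPS Glymphatic Analysis with Synthetic Diffusion Phantoms and Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify glymphatic function from diffusion MRI via the
    DTI-ALPS (diffusion tensor image analysis along the perivascular space)
    index, together with the surrounding analysis pipeline: log-linear
    diffusion-tensor estimation from 4D diffusion-weighted volumes with
    FSL-style bval/bvec gradient tables, fiber-region volume-of-interest
    extraction and the ALPS ratio, CSF/tumor/peritumoral-edema volumetrics
    from integer label masks, and a normality-gated statistical battery
    (two-group and multi-group comparisons with post hoc tests, paired
    hemispheric tests, Spearman correlation matrices, and a two-stage
    univariate-screen-then-multivariable regression with standardized
    coefficients). Includes a Stejskal-Tanner forward simulator that builds
    ventricle-level phantoms with projection and association fiber bands and
    Rician noise, and a Gaussian-copula cohort simulator for glioma/control
    studies, so the whole pipeline can be exercised end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
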