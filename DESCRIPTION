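Package: strainmap
Title: Whole-Brain Strain-Concentration Mapping and Injury Validation for
    Magnetic Resonance Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level biomechanical vulnerability maps of the brain
    from magnetic resonance elastography (MRE) style voxel data. Computes
    strain tensors and octahedral shear strain from complex harmonic
    displacement fields, shear stiffness and strain energy from storage and
    loss moduli, and frequency-dispersion slopes; derives high-strain regions
    from voxelwise one-sample t-maps with Benjamini-Hochberg false discovery
    rate control, cross-validates them by leave-one-out, and validates them
    against apparent fiber density (AFD) deficits in injured cohorts via
    mixed-design ANOVAs, directed contrasts, and a threshold-agnostic binned
    analysis. Includes a seeded voxel-phantom simulator so the whole pipeline
    is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
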