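Package: dwimarkers
Title: Shifted ADC and Signature-Index Markers for Longitudinal Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes microstructure-sensitive diffusion MRI markers from
    two key b-value shells: the shifted apparent diffusion coefficient
    (sADC) and the signature index (Sindex), which locates a tissue's
    two-shell signal between two reference signatures built with the
    diffusion-kurtosis signal model. Provides NIfTI/bval/bvec ingestion,
    voxel-stability quality control, ROI-level pre/post and time-course
    aggregation with outlier filtering and group statistics, and a seeded
    synthetic multi-shell DWI cohort generator for end-to-end validation
    of serial pharmacological-challenge studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
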