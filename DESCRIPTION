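Package: centiloid
Title: Centiloid Calibration of Amyloid PET Tracers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Centiloid standardization pipeline for amyloid
    PET quantification: masked SUVR (standardized uptake value ratio)
    computation on MNI-152-space NIfTI volumes with the whole cerebellum as
    reference region, level-1 pipeline validation against reference Centiloid
    values, level-2 head-to-head calibration of a fluorinated tracer against
    11C-PiB yielding a direct SUVR-to-Centiloid conversion, and cohort quality
    control (young-normal variance ratio and upper-normal-limit thresholds).
    Includes a synthetic phantom and paired-tracer cohort generator so every
    pipeline stage is testable without access to the original scan sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
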