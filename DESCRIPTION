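Package: trialfc
Title: Trial-by-Trial Whole-Brain Functional Co-Activity Mapping for Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies trial-by-trial whole-brain task-evoked activity from
    4D BOLD fMRI runs. For each task trial the temporal Pearson correlation of
    every brain voxel's time course with an ideal haemodynamic response yields
    a whole-brain functional co-activity (FC) map; the spatial correlation
    between FC maps measures trial-to-trial and subject-to-subject similarity,
    supports exhaustive marker-based task identification, and summarizes
    group-level commonality of task-evoked activity. Includes the in-scope
    preprocessing chain (Gaussian spatial smoothing, brick-wall temporal
    bandpass, percent signal change, mask construction), a seeded synthetic
    4D BOLD simulator with ground truth for validation, NIfTI input/output,
    and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
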