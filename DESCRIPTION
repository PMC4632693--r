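Package: putatrophy
Title: Normative Putamen Volumetry and Atrophy Trajectories in Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for age-normative analysis of putamen volume in
    relapsing-remitting multiple sclerosis. Normalizes putamen volume by
    intracranial volume, fits an age-normative regression on healthy
    controls, scores each patient's age-corrected volumetric deviation
    (delta-RPV and delta-RPV percent), and models the deviation against
    disease duration with competing linear and logarithmic fits,
    including atrophy-onset extrapolation and residual-based model
    comparison. Includes a FreeSurfer aseg.stats parser, group-level
    descriptive and comparative statistics, lesion-burden associations,
    a synthetic-cohort generator reproducing the assumed statistical
    structure, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
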