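Package: pupilcf
Title: Detection of Command Following from Task-Evoked Pupil Dilation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for detecting command following from
    automated pupillometry during a mental-arithmetic paradigm. Pupil
    diameter recorded from one eye is segmented into alternating rest and
    task epochs; each task epoch is tested against its flanking rest
    periods with a rank test under Bonferroni correction, and a subject is
    classified as command-following when at least four of five tasks show
    a significant pupillary dilation. Includes baseline pupillary-function
    screening on the Neurological Pupil index, run-chart quality control,
    cohort summaries with Wald risk-ratio comparisons between groups, and
    a seeded generator of synthetic pupil recordings with known ground
    truth for validating the paradigm's operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
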