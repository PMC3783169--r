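Package: loopshift
Title: Chromatin-Complex Gene Annotation, Reconfiguration Inference and
    Nascent-Transcription Metrics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding how genes sit inside higher-order chromatin
    interaction complexes and how those complexes change after a treatment.
    Assembles complexes from ChIA-PET-style anchor pairs, classifies genes as
    anchor, loop or outside genes per condition, infers complex disruption
    from before/after positional transitions, builds consensus cistromes
    across ChIP-seq studies, computes GRO-seq pausing indices and
    spline-scaled metagene profiles, and tests spatial association of
    interval sets by permutation. Ships a self-consistent synthetic-study
    generator with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
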