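Package: blinkscore
Title: Eyeblink-Conditioning Video Scoring and Cerebellar Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring pipeline for delay eyeblink conditioning in head-fixed mice
    together with the cerebellar morphometry measurements used to characterise
    Purkinje cells and vermal anatomy. Converts eyelid videos (multi-page TIFF)
    into white-pixel closure traces, normalises each trial against its
    conditioned- and unconditioned-stimulus anchors, classifies conditioned
    responses with the standard 0.15 threshold-crossing rule (including the
    early-movement exclusion rule and CS-only trial criteria), and aggregates
    percent-CR learning curves and CS-only peak times. Morphometry covers Sholl
    profiles at 8 micrometre steps, distal dendritic spine density with
    every-seventh-branchlet sampling, soma area, arbor height, Purkinje linear
    density and layer thickness. A seeded synthetic-data generator produces
    trial schedules, eyelid kinematics, rendered eye videos, Purkinje-like
    morphologies and cohort tables so every stage of the pipeline can be
    validated against known ground truth. A statistics layer provides the
    unpaired t-tests, two-way (repeated-measures) ANOVAs and
    Bonferroni-corrected planned comparisons used for group reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
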