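Package: embryostage
Title: Morphokinetic Stage Annotation for Time-Lapse Embryo Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating the morphokinetic stages of human
    pre-implantation embryo development from time-lapse imaging.
    Provides the 17-class stage ontology (polar-body appearance through
    hatched blastocyst, plus an empty-well class), frame-level stage
    classifiers (image-only and image + elapsed-time fusion variants) at
    configurable scale, a run-length postprocessing algorithm that
    removes interruptive prediction groups while permitting genuine
    stage reversions such as reverse cleavage, extraction of exact
    stage-transition timings with quantile error analysis, standard
    classification metrics with inverse-class-frequency weighting, and
    a synthetic time-lapse generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
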