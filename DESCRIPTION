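Package: talesim
Title: Tolerance Adaptive Laboratory Evolution: Simulation, Control and
    Mutation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing tolerance adaptive laboratory
    evolution (TALE) experiments, in which serially passaged microbial
    populations are exposed to step-wise increasing stressor concentrations
    under feedback control. Provides a stochastic lineage-level simulator of
    serial-passage batch evolution, the feedback controller that decides when
    to escalate the stressor and how to recover from over-stressed crashes,
    growth-curve analytics (semi-log rate fitting, lag time, cumulative cell
    divisions, plate-to-benchtop OD conversion, green-pixel calibration),
    convergent key-mutation identification from per-isolate mutation tables
    with hypermutator exclusion, genotype clustering, and replicate-level
    clone selection. Worked-example fixtures transcribe the endpoint
    phenotype and key-mutation tables of an ionic-liquid tolerance evolution
    study in Escherichia coli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
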