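Package: hippovasc
Title: Hippocampal Vascular Mapping from Ultrafast Doppler and Confocal Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies hippocampal cerebral blood volume and vascular
    structure from paired imaging modalities. One arm filters ultrafast
    power-Doppler frame stacks with a singular-value-decomposition clutter
    filter whose blood band is selected by maximizing a blood-to-noise
    signal ratio, converts the in-hippocampus signal to decibels referenced
    to the regional maximum, and segments it into intensity quartiles whose
    cut-off values are mouse-independent summaries of the blood-volume
    distribution. The other arm binarizes confocal fluorescence z-stacks of
    lectin-labelled vessels with a per-plane IsoData threshold, labels
    three-dimensional connected vessel components, and expresses each
    vessel as a volume fraction of the hippocampus classified into four
    caliber ranges. A statistics layer runs the cohort workflow
    (Shapiro-Wilk gating, Student's t or Mann-Whitney between ages, one-way
    ANOVA with Bonferroni or Friedman with a Benjamini-Krieger-Yekutieli
    two-stage step-up within age), and seeded synthetic-data generators
    provide Doppler scenes, tubular vessel phantoms and cohort tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
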