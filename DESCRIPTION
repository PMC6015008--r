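Package: switchpupil
Title: Pupillometry and Looking-Time Analysis for Infant Switch-Paradigm Experiments
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for time-resolved pupillometry in infant
    switch-paradigm studies: reading and writing long-format 120-Hz binocular
    gaze exports, missing-data bookkeeping and linear gap interpolation,
    zero-phase 4-Hz low-pass filtering, binocular averaging, pre-stimulus
    baseline correction and 50-ms binning, proportion-of-looking-time measures,
    per-bin repeated-measures ANOVA with partial eta-squared, the
    consecutive-bin significance rule, Bonferroni post-hoc paired tests,
    Hedges' g effect sizes for within- and between-participant designs, and a
    cluster-based Monte-Carlo permutation correction for the time-course
    multiple-comparison problem. Includes a synthetic-session generator that
    emulates the trial structure, blink/dropout process, and the fast
    (perceptual-novelty) and slow (association-novelty) dilation components of
    such experiments, so that the whole pipeline is testable without access to
    infant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
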