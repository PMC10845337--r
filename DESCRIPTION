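Package: layoutstudy
Title: Design, Simulation and Analysis of Perceptual Studies of 2D Layouts for 3D Spatial Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiple-choice perceptual studies that compare how well
    circular, half-matrix and full adjacency-matrix layouts convey a single
    spatial contact on a segmented chain (the kind of pairwise connectivity
    data produced by chromosome-conformation-capture experiments). The package
    enumerates the admissible contact set on an n-segment chain, constructs
    inverted-answer distractors, builds randomized surveys with duplicated
    questions, draws deterministic vector graphics for all three layouts,
    simulates participant cohorts with layout-dependent accuracy, inversion
    propensity, sequence-proximity bias and decay-to-plateau response times,
    and runs the full analysis battery: duplicate-question consistency with a
    randomness threshold, accuracy, an error taxonomy (inversion, inverted
    missing, other), inter-segment distance and MinDistance scores, learning
    curves, and inferential tests (one-way ANOVA with Tukey post hoc, pairwise
    Pearson chi-squared, Kruskal-Wallis with Dunn post hoc) under a
    configurable multiple-testing adjustment.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
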