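Package: bodymapr
Title: Quantitative Analysis of Digital Body-Map Symptom Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents tablet-acquired body-map symptom drawings (per-view
    rasters of visual-analog-scale intensities restricted to a body outline)
    and quantifies their test-retest reproducibility: symptom extent in
    pixels, connected-cluster counts under 4- or 8-connectivity, and Jaccard
    overlap of symptom patterns, per body view and pooled over views.
    Provides the agreement statistics used in reproducibility studies of
    pain drawings (two-way mixed-model ICC(3,1) with F-based confidence
    intervals, Bland-Altman limits of agreement, two-sample t tests from
    summary statistics, and ICC sample-size planning from expected
    confidence-interval width), scoring for the SUS, AttrakDiff 2 and
    ISONORM 9241/10 usability instruments, a synthetic test-retest cohort
    generator with a known perturbation model, and PNG/NIfTI/CSV input and
    output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    png,
    RNifti,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
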