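Package: revpitch
Title: Reverse-Correlation Analysis of Pitch-Contour Mental Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reverse-correlation (classification-image) experiments on
    pitch contours. Generates Gaussian pitch-noise stimuli in cents over a small
    number of breakpoints, builds two-alternative forced-choice (2AFC) trial
    pairings, renders harmonic-complex audio for validation, simulates linear
    template observers with internal noise and lapses, estimates first-order
    temporal kernels from session logs, computes RMS sensitivity and
    agreement-based internal-noise indices, selects polynomial kernel shapes by
    nested F-tests, and runs cohort-level group comparisons (per-timepoint Welch
    tests, intra-group kernel variability, exceptional-sensitivity subgroups).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
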