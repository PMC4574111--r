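Package: rhythmskills
Title: Scoring and Dissociation Analysis of Beat-Tapping and Rhythm-Memory Skills
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-test rhythm battery: construction of metronome,
    tempo-adaptation, drum-along and sequence-memory stimulus schedules;
    extraction of drum onsets from continuous two-channel recordings by
    amplitude threshold with a refractory period; the four test-scoring
    procedures (normalized inter-onset-interval variability, tempo-adaptation
    error, hit/rest grid agreement, delayed-reproduction grid agreement); a
    synthetic-cohort simulator built on a linear phase- and period-correction
    tapping model with two-source timing noise; and the cohort-level
    statistics used to test whether beat tapping and rhythm memory are
    dissociable skills (outlier exclusion, log and rationalized-arcsine
    transforms, Jarque-Bera normality checks, Pearson correlation matrices,
    generalized least squares factor analysis with varimax rotation, and
    hierarchical regressions against verbal memory).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
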