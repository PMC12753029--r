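Package: uhrspeech
Title: Linguistic and Acoustic Speech Biomarkers for Ultra-High-Risk Psychosis Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for short (45 second) timed
    speech recordings in ultra-high-risk (UHR) psychosis cohorts: extraction
    of linguistic features (words per minute, articulation rate, dysfluency,
    sequential coherence) from time-aligned transcripts and acoustic features
    (fundamental-frequency mean and SD, intensity mean and SD, HF500) from
    mono WAV audio; covariate-adjusted per-feature linear models with pairwise
    outcome-group contrasts and Benjamini-Hochberg correction; and one-vs-all
    outcome prediction with class-weighted linear support vector machines
    under nested (leave-one-out outer, stratified k-fold inner)
    cross-validation, evaluated by balanced accuracy with bootstrap confidence
    intervals. A synthetic speech-cohort generator with controllable group
    effects provides ground truth for every stage, so the whole pipeline is
    verifiable without access to protected clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
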