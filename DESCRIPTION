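Package: remsacc
Title: Saccade Detection and Phasic/Tonic REM Microstructure from Single-Channel EOG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphology-aware detection of saccadic eye movements in a single
    electrooculography (EOG) channel during REM sleep, and reconstruction of
    the phasic/tonic REM microstructure. Implements per-REM-interval
    preprocessing (baseline removal, zero-phase band-pass filtering,
    z-scoring), hybrid adaptive segmentation fusing a median-absolute-
    deviation amplitude-change score with a matched-filter morphology score
    from a data-derived saccade kernel, derivative-extremum boundary
    refinement, a two-feature RBF support-vector-machine segment classifier
    (saccade/blink/artifact), saccadic-burst grouping, event-level evaluation
    metrics with a fragmentation/merging taxonomy, and a synthetic EOG
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
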