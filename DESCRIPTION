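Package: fcreliab
Title: Test-Retest Reliability of fMRI Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the test-retest reliability of fMRI
    functional connectivity (FC) across rest and task states. Implements
    split-half FC test-retest correlation (FC-TRC), edge-wise intraclass
    correlation ICC(2,1) with its two-way random-effects variance
    decomposition, temporal BOLD signal properties (tMean, tSD, tSNR) and
    their task-vs-rest deltas, motion censoring by framewise displacement
    with volume matching across states, temporal cleaning (detrending,
    band-pass filtering, confound regression), finite impulse response
    (FIR) task regression with averaged-bin contrasts and residualized
    connectomes, consensus functional-network assignment by community
    detection on density-thresholded connectomes, and parcel-wise mixed
    models attributing reliability to signal properties and task effects.
    Includes a multi-subject, multi-session synthetic BOLD generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    igraph,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
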