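Package: eegReliability
Title: Test-Retest Reliability of EEG Connectivity, Complexity and
    Spanning-Tree Network Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sensor-level resting-state EEG reliability analysis. Computes
    phase lag index (PLI), corrected amplitude envelope correlation (AECc),
    permutation entropy (PE) and inverted joint permutation entropy (JPE)
    from band-filtered, epoched multichannel recordings; characterises the
    maximum spanning tree of each connectivity matrix (leaf fraction, degree,
    diameter, betweenness centrality, eccentricity, tree hierarchy, edge
    overlap between recordings); and quantifies test-retest reliability of
    the resulting scalar measures with two-way mixed-effects intraclass
    correlation coefficients, F-based and bootstrap confidence intervals,
    Koo & Li reliability categories, and a four-way state/temporal biomarker
    classification. A synthetic coupled-oscillator cohort generator with
    known variance components provides ground truth for end-to-end
    parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
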