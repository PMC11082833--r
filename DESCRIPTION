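Package: ptrburst
Title: Mass-Univariate Burst Analysis of Post-Task Responses in
    Source-Space Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises transient oscillatory bursts that
    drive post-task responses (PTRs) in parcellated source-space
    electrophysiological recordings. Fits a three-state time-delay
    embedded hidden Markov model (TDE-HMM) independently to each brain
    region, groups states across regions by k-means clustering of their
    binary timecourses, identifies the PTR state cluster from
    trial-averaged state probability evolutions, and summarises the burst
    state by lifetime statistics, multitaper band power, oscillations per
    burst, burst rate and coincidence, and time-frequency reconstruction.
    Includes condition contrasts and behaviour correlations, and a
    synthetic-data generator with ground-truth burst annotations for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
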