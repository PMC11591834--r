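Package: plvnet
Title: Phase-Locking Brain Networks from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("plvnet", "developers", email = "plvnet@example.org",
           role = c("aut", "cre"))
Description: Characterizes functional brain networks from multichannel
    resting-state EEG across frequency bands. Implements zero-phase band
    filtering, epoching, amplitude-based artifact rejection and common
    average referencing; phase-locking value (PLV) connectivity via the
    analytic signal; sparsity-thresholded undirected network construction;
    graph-theoretic node and edge metrics (betweenness centrality, nodal
    efficiency, clustering coefficients, characteristic path length) on a
    Floyd-Warshall shortest-path core; and paired condition comparisons
    (Shapiro-Wilk gated t / Wilcoxon signed-rank tests) with
    Benjamini-Hochberg false-discovery-rate control. Ships a synthetic EEG
    generator with analytically known pairwise phase locking so the whole
    pipeline is testable end to end without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
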