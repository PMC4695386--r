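Package: replayvta
Title: Hippocampal Replay Decoding and VTA Unit Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking ventral tegmental area (VTA) unit
    activity to hippocampal sharp wave-ripple (SPW-R) replay. Provides
    clusterless (marked point-process) Bayesian reconstruction of position
    and run direction from tetrode amplitude marks, SPW-R and slow-wave-sleep
    frame detection from multiunit activity, constant-speed trajectory
    fitting with column-cycle and pseudo-event Monte Carlo shuffles for
    replay classification, VTA unit characterization (reward responsiveness,
    waveform features, peri-event modulation with bootstrap significance,
    von Mises theta phase locking), reward-site-bias statistics with
    chi-square and permutation logistic-regression interaction tests, and a
    synthetic session generator with exported ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
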