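Package: pedalcoi
Title: Co-Contraction Analysis and Auditory Biofeedback Simulation for Pedaling sEMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses surface electromyography (sEMG) recorded
    during cycling. Generates synthetic multi-channel sEMG and crank-marker
    trajectories with known crank-phase-locked activation templates, segments
    pedaling cycles at the upper dead center, extracts zero-phase Butterworth
    linear envelopes on a 200-point cycle base, computes the common-area
    co-contraction index (COI) for agonist-antagonist muscle pairs, simulates
    a threshold-based auditory sEMG biofeedback system (calibration, beep
    events, overlap metrics, tone rendering), and compares COI across feedback
    conditions with one-way repeated-measures ANOVA and partial eta squared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
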