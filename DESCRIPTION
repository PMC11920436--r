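Package: clsleep
Title: Closed-Loop Slow-Oscillation Auditory Stimulation and Sleep EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop targeted memory
    reactivation (TMR) during sleep. Generates synthetic NREM sleep EEG with
    planted slow oscillations and spindles, hypnograms, cue sounds and serial
    reaction time task (SRTT) behavior with known ground truth; simulates
    real-time slow-oscillation phase-targeted auditory stimulation using an
    endpoint-corrected Hilbert transform phase estimator with online validation
    and dynamic condition balancing; detects slow oscillations and sleep
    spindles offline; computes cue- and trough-locked event-related potentials
    and Hanning-taper time-frequency power with cluster-based permutation
    statistics; and runs the behavioral consolidation analysis (offline gains,
    TMR index, repeated-measures ANOVA with Greenhouse-Geisser correction and
    FDR posthocs).
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
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
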