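Package: ephyr
Title: Synthetic-Ground-Truth Analysis of Hippocampal Synaptic Events,
    Network Bursts and Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for hippocampal electrophysiology: detection of
    spontaneous postsynaptic currents and slow network bursts in voltage-clamp
    traces; multi-electrode-array (MEA) spike and Poisson-surprise burst
    detection with a spatial connected-component analysis of activity
    propagation triggered on dentate-gyrus spikes; awake local-field-potential
    analysis with Morlet band power, theta-phase to gamma-power coupling
    profiles compared by an extra-sum-of-squares F test, and envelope
    z-score (Kay-style) ripple detection; and the group-comparison statistics
    used with such data. Because raw recordings of this kind are rarely
    deposited, the package ships synthetic-data generators with exact ground
    truth for all three recording classes, so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
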