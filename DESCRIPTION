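Package: vo2tcn
Title: Oxygen-Uptake Prediction from Wearable Cardiorespiratory Signals
    with Temporal Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Second-by-second prediction of oxygen uptake (VO2) during
    cycling exercise from 1 Hz cardiorespiratory channels (work rate,
    heart rate, heart-rate reserve, breathing frequency, minute
    ventilation) using a causal dilated temporal convolutional network
    with residual blocks and a tunable receptive field.  Includes a
    synthetic cardiorespiratory simulator (first-order on/off kinetics,
    pseudorandom binary sequence and ramp-incremental cycling protocols,
    breath-by-breath measurement noise), the preprocessing chain
    (5-breath median filter, 1 Hz interpolation, cross-correlation time
    alignment, ventilation calibration, feature scaling, sliding-window
    extraction), ramp-test analytics (VO2peak, mean response time,
    protocol work-rate derivation), participant-level training with grid
    search, and evaluation statistics (repeated-measures Bland-Altman
    agreement, per-protocol error summaries, MET-based physical-activity
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
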