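Package: cogload
Title: Event-Locked EEG Band Power, Pupillometry, and N-Back Workload
    Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing cognitive-workload experiments built around
    the N-back continuous-recognition task: stimulus-sequence derivation,
    generation and scoring; event-locked event-related desynchronization and
    synchronization (ERD/ERS) band-power analysis of multichannel EEG with
    per-stimulus ("near") and resting ("away") baselines; per-stimulus
    eye-movement and pupillometry workload metrics with capture-rate
    screening; rank-based condition comparisons in the Measure/N/Mean/SD/
    Median/W/p table schema; and a synthetic-session generator (behaviour,
    EEG, gaze) with known ground truth for end-to-end validation.
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
    withr
Config/testthat/edition: 3
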