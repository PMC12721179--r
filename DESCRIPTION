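Package: gaitdecode
Title: Walking-Bout Kinematics, Gait-Phase Tuning and Population Decoding of
    Locomotion from Limb Tracking and Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spontaneous locomotion from high-speed
    limb tracking together with simultaneously recorded single-unit spike
    trains. Segments walking bouts from whole-body speed and acceleration,
    extracts per-limb stride cycles and instantaneous gait phase via the
    analytic signal of band-passed limb displacement, quantifies single-unit
    tuning (peri-onset modulation, speed correlation, spike-phase vector
    length with a spike-jitter null), and decodes time around walking onset,
    body speed and gait phase from pseudo-population activity with
    one-against-one support-vector-machine ensembles and shuffle controls.
    Includes an inhomogeneous-Poisson synthetic-session generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    data.table,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
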