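Package: gaitcoupling
Title: Spike-Gait-Phase Coupling Analysis for Freely Walking Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to link striatal single-unit spiking to single-limb gait
    in freely behaving mice. Segments strides and walking bouts from tracked
    keypoint trajectories, assigns a per-frame gait phase to each limb,
    quantifies spike coupling to the gait cycle with circular resultant
    statistics and a spike-time jitter null, classifies whole-body start/stop
    and speed coding, identifies optogenetically tagged units with
    latency/waveform criteria, and compares groups of units with an angular
    permutation test. Includes a synthetic-data generator with known
    ground-truth gait and coding parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
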