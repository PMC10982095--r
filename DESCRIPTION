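Package: bodycues
Title: Kinematic Cues to Deception from Motion-Capture Interviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-mining pipeline for bodily cues to deception in seated
    motion-capture interviews. Encodes 23-joint position recordings as 67
    geometric features of four types (movement, joint angle, joint distance,
    posture symmetry), aggregates them over non-overlapping time windows with
    five summary statistics into 335-dimensional vectors, and classifies
    truthful versus deceptive sessions with per-feature Gaussian naive Bayes
    combined by significance-filtered majority voting under
    leave-one-interviewee-out cross-validation. Includes a synthetic corpus
    generator with a controllable deception effect size, CSV session and
    manifest input/output, and the systematic experiments of the underlying
    study design: train/test-set crossings, window-length, feature-count and
    measurement-noise sweeps, and per-feature and per-body-part breakdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
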