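Package: pupilnum
Title: Pupillary Light-Response Gain Under Numerosity Adaptation
Version: 0.1.0
Authors@R:
    person("Pupilnum", "Developers", email = "pupilnum@example.org",
           role = c("aut", "cre"))
Description: Tools to construct area-matched dot-array stimuli for numerosity
    adaptation experiments, to simulate eye-tracker-style pupil recordings and
    verbal numerosity estimates with a known generative structure, to clean and
    normalize event-locked pupil traces (artifact rejection, saccade-trial
    exclusion, down-sampling, per-participant z-scoring, median baseline
    correction), to extract peak-constriction and pre-test pupil features, and
    to fit the trial-level mixed-effects models and individual-differences
    correlation used to quantify how adaptation changes the gain of the
    pupillary light response.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
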