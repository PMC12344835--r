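Package: gapeyetrack
Title: Gap-Overlap Eye-Tracking and Pupillometry Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trial-level analysis of the gap-overlap attention-disengagement
    paradigm from raw gaze and pupil samples: randomized session schedules,
    velocity-threshold (I-VT) event detection, gaze-shift latency and
    no-shift extraction with anticipatory/improbable exclusion rules, pupil
    preprocessing (blink interpolation, moving-median filtering, baseline
    subtraction, phasic dilation amplitude, MAD outlier removal), and a
    statistics layer of trial-level mixed models with Satterthwaite degrees
    of freedom, Bonferroni-adjusted marginal-mean contrasts,
    contrast-of-contrasts, and per-group logistic odds ratios linking pupil
    dilation to no-shift probability. Includes a synthetic-session simulator
    with known ground truth so the full pipeline is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
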