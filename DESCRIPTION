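Package: chasedot
Title: Simulation and Mixed-Model Analysis of Chase-Detection Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates the moving-dot displays of the wolf/sheep chase-detection
    paradigm used in animacy-perception research (random-walk distractors, a
    chasing dot whose heading is constrained to an angular window centred on its
    target, social gaze and non-social luminance cues), builds counterbalanced
    within-participant trial designs, simulates trial-by-trial detection
    responses from a random-intercept logistic generative model or from
    trajectory-based heuristic observers, and fits the corresponding
    random-intercept logistic regression with Wald tests, d-prime and accuracy
    summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
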