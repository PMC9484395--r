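Package: wristcoda
Title: Movement Behaviour Classification and Compositional Survival
    Analysis for Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for studying 24-hour movement behaviours (sleep,
    sedentary behaviour, light physical activity, moderate-to-vigorous
    physical activity) measured by wrist-worn tri-axial accelerometers.
    Provides quality control and autocalibration of raw traces, non-wear
    detection, rotation-invariant epoch feature extraction, behaviour
    classification with a balanced random forest smoothed by a hidden
    Markov model (Viterbi decoding), leave-one-participant-out evaluation,
    minute-of-day imputation into daily 24-hour behaviour compositions,
    and compositional survival analysis: isometric log-ratio pivot
    coordinates, Cox proportional-hazards models on the age timescale,
    time-reallocation hazard ratios, proportional-hazards diagnostics and
    E-values for unmeasured confounding. Includes synthetic generators for
    labelled wrist signals and survival cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
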