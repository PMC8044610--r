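Package: echosdt
Title: Signal Detection Analysis of Echo-Detection and Echo-Localization
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-task human-echolocation psychophysics built on
    equal-variance signal detection theory (SDT). Provides closed-form
    transformations between hit/false-alarm rates and the sensitivity index
    d' and response criterion c; a seeded generative simulator of a
    constant-stimulus echo-detection vs. echo-localization experiment
    (reflector distances on a rail, randomized left/right/absent reflector
    positions, practice-day exclusion); Bayesian estimation of per-participant
    SDT parameters under a categorical-distance model (d' and c per task and
    distance) and an exponential-distance model (d' decaying exponentially
    with reflector distance), with weakly informative normal priors, posterior
    medians, 95% highest-posterior-density intervals and convergence
    diagnostics; draw-wise task contrasts and response-bias tables; a
    repeated-measures Task-by-Distance ANOVA with partial eta-squared effect
    sizes; and an idealized collinear echo-delay geometry relating interclick
    interval to reflector distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
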