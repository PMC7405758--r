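Package: pursuitloc
Title: Relative Flash Localization During Fixation and Smooth Pursuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-flash relative localization experiments
    during fixation and smooth pursuit eye movements: synthetic observer and
    500-Hz gaze-trace simulation, saccade/blink detection and trial-level
    quality control, maximum-likelihood cumulative-Gaussian psychometric
    fitting with bootstrap confidence intervals for the point of subjective
    equality (PSE), linear regression of absolute mislocalization against
    retinal eccentricity, and comparison of four reference-frame models
    (screen- vs eye-centered, with and without an eccentricity effect) of
    relative mislocalization, with paired t tests, Cohen's dz, and sequential
    Bonferroni (Holm) correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    signal,
    jsonlite,
    readr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
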