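Package: oudrive
Title: Binocular Visual Field Integration and Driving-Simulator
    Vehicle-Control Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a binocular (OU) visual field index from pairs of
    monocular Humphrey-style threshold and total-deviation maps by
    quadratic summation of linear sensitivities, with an
    eccentricity-weighted five-ring visual field index. Computes
    vehicle-control outcome measures (velocity, steering and acceleration
    variability, over-limit fractions) from driving-simulator telemetry
    and scores an in-cab stimulus-detection visual field task. Includes a
    synthetic cohort generator with plantable regression effects and a
    linear mixed-model analysis stage (Kenward-Roger degrees of freedom)
    relating vehicle control to visual field loss, neurocognitive scores
    and vision-related quality of life.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    pbkrtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
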