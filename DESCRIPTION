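Package: thermoperf
Title: Thermal Exercise and Metabolic Performance Analysis for Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes intermittent-closed respirometry oxygen traces,
    tracked burst-escape (C-start) trajectories, exhaustive-chase swim
    records and plate-reader enzyme assays into standard fish performance
    metrics: standard and maximum metabolic rate (SMR, MMR), absolute
    aerobic scope, excess post-exercise oxygen consumption (EPOC) and
    recovery time, burst velocity and acceleration, chase swim speed and
    exercise effort, and enzyme activity rates. A thermal-sensitivity
    engine computes interval-wise Q10 and percent-change statistics with
    omnibus summaries for comparing acute temperature exposure against
    acclimation, plus the accompanying inferential layer (one- and
    two-way ANOVA with Tukey HSD, Levene's test, and effort-EPOC
    regression with slope comparison). A seeded synthetic-data generator
    with closed-form ground truth supports estimator validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
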