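Package: adipoage
Title: Adiposity-Modulated Brain Ageing from Structural Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how adiposity modulates age-related change in
    brain structure in cross-sectional cohorts. Provides a seeded synthetic
    cohort generator with the statistical structure of a population ageing
    study (inverted-U white-matter volume trajectory, age-correlated BMI,
    age-dependent reconstruction quality), study inclusion/exclusion and
    Bland-Altman edit-agreement preprocessing, penalized-spline (P-spline)
    age-trajectory regression with GCV/REML smoothing selection and
    age-by-BMI interaction tests, and the volume-matched brain-age-difference
    estimator between lean and overweight/obese groups with constrained
    percentile bootstrap confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
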