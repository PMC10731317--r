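Package: canideye
Title: Iris-Pupil Colour Contrast in Canids and Human Perception of Dog Eye Colour
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing eye colour between domestic dogs and grey
    wolves and for analysing how dog eye colour shapes human impressions.
    Converts sRGB eye photographs to CIE LAB, summarises colour over
    iris/pupil region masks with specular-highlight exclusion, and computes
    the per-channel Michelson-type iris-pupil contrast. Provides Welch
    two-sample comparisons with effect sizes, Horn's parallel analysis and
    maximum-likelihood factor analysis with varimax rotation for personality
    rating scales, paired eye-colour tests, MANOVA, and Gaussian linear mixed
    models with Type III Wald tests for acceptance attitudes. A synthetic-data
    module renders parametric eye images with ground-truth masks and simulates
    counterbalanced questionnaire data from a two-factor latent model so the
    whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    mgcv,
    lme4,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
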