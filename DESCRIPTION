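Package: audiotwin
Title: Twin Modelling of Age-Related Hearing Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of age-related hearing
    impairment in classical twin designs. Simulates twin cohorts with known
    additive-genetic (A), common-environment (C) and unique-environment (E)
    structure in audiogram and speech-in-noise traits; constructs scalar
    audiogram phenotypes (pure-tone average, better-ear hearing level,
    principal-component scores and their difference) and ranks them by
    age correlation and audiogram-shape capture; fits univariate ACE/AE/CE/E
    and bivariate correlated-factors variance-component models by maximum
    likelihood with profile-likelihood confidence intervals; simulates the
    adaptive digit-triplet speech-in-noise staircase; and validates a
    speech-to-noise-ratio screening test against audiometric references
    with ROC, Bland-Altman and Pitman repeatability analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
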