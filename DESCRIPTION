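Package: fertdiff
Title: Education-Specific Cohort Fertility Forecasting by Diffusion Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts education- and age-specific period fertility rates into
    completed cohort fertility along cohort diagonals, completes truncated
    cohorts with a Lee-Carter extrapolation, estimates education-specific
    diffusion rates per unit change in skills-adjusted mean years of schooling
    (SLAMYS), and projects future cohorts with a multiplicative recurrence.
    Also fits strata-level fixed- and random-effect Poisson models of ideal
    family size and children ever born from DHS-like survey microdata, with
    education-specific prediction curves over stratum mean schooling.  Includes
    seeded generators for every pipeline input, an out-of-sample validation
    protocol, and a command-line interface over YAML run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
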