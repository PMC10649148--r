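Package: shrinkbmi
Title: Height-Corrected BMI Analysis for Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how age-related height loss distorts body mass
    index (BMI) in longitudinal cohort data. Provides per-subject LOWESS
    smoothing of height and BMI trajectories with two-threshold outlier
    rejection, construction of the "young height" (mean stature at ages 40 and
    under) and the corrected BMI computed from it, age-resolved
    overweight/obesity misclassification fractions, obese versus non-obese
    relative risks for pre-diabetes, diabetes and hypertension under current
    versus corrected BMI, and population trend fits of height loss and excess
    BMI. Includes a calibrated synthetic longitudinal cohort generator with a
    latent truth table for parameter-recovery testing.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
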