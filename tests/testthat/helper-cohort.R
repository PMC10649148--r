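# Measurement-noise-free configuration; shrinkage and BMI drift optional.
# With shrink = FALSE and drift = 0 every trajectory is exactly constant,
# so LOWESS is exact and current/corrected BMI coincide by construction.
noise_free_config <- function(n = 200, shrink = TRUE, drift = 0.05,
                              female_fraction = 0.5, seed = 99, ...) {
  sim_config(
    n_subjects = n,
    female_fraction = female_fraction,
    height_noise_sd = 0,
    bmi_noise_sd = 0,
    outlier_prob = 0,
    rounding_enabled = FALSE,
    bmi_age_drift = drift,
    shrink_rate_f = if (shrink) 0.12 else 0,
    shrink_rate_m = if (shrink) 0.09 else 0,
    shrink_rate_sd = if (shrink) 0.02 else 0,
    seed = seed,
    ...
  )
}

# build a smoothed_series by hand (for oracle-composition tests)
make_series <- function(age, raw, fitted = raw, outlier = rep(FALSE, length(age)),
                        smoothed = TRUE) {
  shrinkbmi:::new_smoothed_series(age, raw, fitted, outlier, smoothed)
}

# minimal subject-summary table for the classification/risk modules
make_summaries <- function(subject_id, sex, age, current_bmi, corrected_bmi,
                           ...) {
  tibble::tibble(subject_id = subject_id, sex = sex, age = age,
                 current_bmi = current_bmi, corrected_bmi = corrected_bmi, ...)
}
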