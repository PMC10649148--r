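#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles every knob of [simulate_cohort()] into a validated list. The
#' defaults are calibrated so that the simulated population reproduces the
#' anthropometric structure the analysis pipeline assumes: biennial exams from
#' an enrollment age below 40 up to age 80, a mean height loss over ages
#' 40--80 of 4.8 cm for women (0.12 cm/yr over 40 years) and 3.6 cm for men
#' (0.09 cm/yr), young-adult BMI spanning roughly 17--35 kg/m2 for women and
#' 19--35 for men, and disease prevalences whose obese vs non-obese ratio
#' equals the configured relative risks exactly in expectation.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param female_fraction Proportion of women, in `[0, 1]`.
#' @param enroll_age_range Two ages (years); enrollment drawn uniformly
#'   between them. Must lie below 40 so every subject is eligible for the
#'   young-height construction.
#' @param exam_interval Years between successive exams.
#' @param final_age Last age (years) at which an exam can occur.
#' @param young_height_mean_f,young_height_mean_m Mean young-adult height (cm).
#' @param young_height_sd Between-subject SD of young-adult height (cm).
#' @param shrink_onset_age Age (years) at which height loss begins.
#' @param shrink_rate_f,shrink_rate_m Mean height-loss rate (cm/yr) after
#'   onset. The defaults give 4.8 cm (women) and 3.6 cm (men) over ages 40--80.
#' @param shrink_rate_sd Between-subject SD of the loss rate (cm/yr); the
#'   subject-level rate is truncated at zero (no growth in adulthood).
#' @param young_bmi_mean_f,young_bmi_mean_m Mean young-adult BMI (kg/m2).
#' @param young_bmi_sd Between-subject SD of young-adult BMI (kg/m2).
#' @param young_bmi_range_f,young_bmi_range_m Truncation bounds (kg/m2) for
#'   the young-adult BMI draw.
#' @param bmi_age_drift Within-subject BMI drift (kg/m2 per year) after age 40.
#' @param bmi_noise_sd SD (kg/m2) of exam-to-exam BMI fluctuation (weight
#'   fluctuation expressed on the BMI scale).
#' @param height_noise_sd SD (cm) of height measurement noise.
#' @param outlier_prob Per-exam probability of a gross height recording error.
#' @param outlier_magnitude Two values (cm): range of the gross-error
#'   magnitude; the sign is random.
#' @param prediab_base,diab_base,htn_base Length-2 numerics `c(intercept,
#'   slope)`: non-obese prevalence at age `a` is
#'   `intercept + slope * (a - 40)`, clamped to `[0, 1]`.
#' @param rr_prediab_f,rr_prediab_m,rr_diab_f,rr_diab_m,rr_htn_f,rr_htn_m
#'   True prevalence ratios (obese vs non-obese) used to scale the base
#'   prevalence for subjects whose true (young-height) BMI is >= 30.
#' @param med_fraction Fraction of hypertensive subject-exams coded as taking
#'   antihypertensive medication.
#' @param controlled_fraction Fraction of medicated hypertensive exams whose
#'   measured blood pressure is below the diagnostic thresholds (controlled
#'   hypertension; the medication flag alone carries the diagnosis).
#' @param rounding_enabled Apply the archival measurement conventions: height
#'   floored to the next lower quarter inch, weight rounded to the nearest
#'   5 lb. See [measurement_model()].
#' @param seed Integer seed; the default seed used by [simulate_cohort()].
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 7)
#' cfg$shrink_rate_f * 40 # implied mean loss, ages 40-80, women
sim_config <- function(n_subjects = 1000,
                       female_fraction = 0.5,
                       enroll_age_range = c(30, 38),
                       exam_interval = 2,
                       final_age = 80,
                       young_height_mean_f = 160.5,
                       young_height_mean_m = 174.0,
                       young_height_sd = 6.0,
                       shrink_onset_age = 40,
                       shrink_rate_f = 0.12,
                       shrink_rate_m = 0.09,
                       shrink_rate_sd = 0.02,
                       young_bmi_mean_f = 25.5,
                       young_bmi_mean_m = 26.0,
                       young_bmi_sd = 3.5,
                       young_bmi_range_f = c(17, 35),
                       young_bmi_range_m = c(19, 35),
                       bmi_age_drift = 0.05,
                       bmi_noise_sd = 0.3,
                       height_noise_sd = 0.5,
                       outlier_prob = 0.01,
                       outlier_magnitude = c(2.5, 10),
                       prediab_base = c(0.05, 0.004),
                       rr_prediab_f = 2.8,
                       rr_prediab_m = 2.4,
                       diab_base = c(0.01, 0.002),
                       rr_diab_f = 3.5,
                       rr_diab_m = 2.8,
                       htn_base = c(0.10, 0.008),
                       rr_htn_f = 1.5,
                       rr_htn_m = 1.8,
                       med_fraction = 0.5,
                       controlled_fraction = 0.5,
                       rounding_enabled = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    female_fraction = female_fraction,
    enroll_age_range = as.numeric(enroll_age_range),
    exam_interval = exam_interval,
    final_age = final_age,
    young_height_mean_f = young_height_mean_f,
    young_height_mean_m = young_height_mean_m,
    young_height_sd = young_height_sd,
    shrink_onset_age = shrink_onset_age,
    shrink_rate_f = shrink_rate_f,
    shrink_rate_m = shrink_rate_m,
    shrink_rate_sd = shrink_rate_sd,
    young_bmi_mean_f = young_bmi_mean_f,
    young_bmi_mean_m = young_bmi_mean_m,
    young_bmi_sd = young_bmi_sd,
    young_bmi_range_f = as.numeric(young_bmi_range_f),
    young_bmi_range_m = as.numeric(young_bmi_range_m),
    bmi_age_drift = bmi_age_drift,
    bmi_noise_sd = bmi_noise_sd,
    height_noise_sd = height_noise_sd,
    outlier_prob = outlier_prob,
    outlier_magnitude = as.numeric(outlier_magnitude),
    prediab_base = as.numeric(prediab_base),
    rr_prediab_f = rr_prediab_f,
    rr_prediab_m = rr_prediab_m,
    diab_base = as.numeric(diab_base),
    rr_diab_f = rr_diab_f,
    rr_diab_m = rr_diab_m,
    htn_base = as.numeric(htn_base),
    rr_htn_f = rr_htn_f,
    rr_htn_m = rr_htn_m,
    med_fraction = med_fraction,
    controlled_fraction = controlled_fraction,
    rounding_enabled = isTRUE(rounding_enabled),
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  num <- vapply(cfg[!(names(cfg) %in% "rounding_enabled")], is.numeric, logical(1))
  if (!all(num)) {
    rlang::abort(paste0("non-numeric sim_config field(s): ",
                        paste(names(num)[!num], collapse = ", ")),
                 class = "shrinkbmi_config_error")
  }
  vals <- unlist(cfg[!(names(cfg) %in% "rounding_enabled")])
  if (any(!is.finite(vals))) {
    rlang::abort("sim_config fields must be finite", class = "shrinkbmi_config_error")
  }
  check <- function(ok, msg) {
    if (!ok) rlang::abort(msg, class = "shrinkbmi_config_error")
  }
  check(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  for (p in c("female_fraction", "outlier_prob", "med_fraction", "controlled_fraction")) {
    check(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  }
  for (s in c("young_height_sd", "shrink_rate_sd", "young_bmi_sd", "bmi_noise_sd",
              "height_noise_sd", "shrink_rate_f", "shrink_rate_m",
              "young_height_mean_f", "young_height_mean_m",
              "exam_interval")) {
    check(cfg[[s]] >= 0, paste(s, "must be non-negative"))
  }
  check(cfg$exam_interval > 0, "exam_interval must be positive")
  check(length(cfg$enroll_age_range) == 2 && diff(cfg$enroll_age_range) >= 0,
        "enroll_age_range must be two non-decreasing ages")
  check(cfg$enroll_age_range[2] < 40,
        "enrollment must complete before age 40 (young-height eligibility)")
  check(cfg$shrink_onset_age < cfg$final_age,
        "shrink_onset_age must precede final_age")
  check(cfg$final_age > 40 + cfg$exam_interval,
        "final_age must leave room for exams after age 40")
  for (rr in c("rr_prediab_f", "rr_prediab_m", "rr_diab_f", "rr_diab_m",
               "rr_htn_f", "rr_htn_m")) {
    check(cfg[[rr]] > 0, paste(rr, "must be positive"))
  }
  for (rng in c("young_bmi_range_f", "young_bmi_range_m", "outlier_magnitude")) {
    check(length(cfg[[rng]]) == 2 && diff(cfg[[rng]]) >= 0 && all(cfg[[rng]] > 0),
          paste(rng, "must be two positive non-decreasing values"))
  }
  cfg
}

#' Read a simulation configuration from a YAML or flat key-value file
#'
#' Keys must match the arguments of [sim_config()]; unknown keys are an error.
#' Omitted keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `"sim_config"` list.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown sim_config key(s): ", paste(bad, collapse = ", ")),
                 class = "shrinkbmi_config_error")
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects, ",
      round(100 * x$female_fraction), "% female, exams every ",
      x$exam_interval, " y to age ", x$final_age, "\n", sep = "")
  cat("  shrink rates (cm/yr): F ", x$shrink_rate_f, ", M ", x$shrink_rate_m,
      " (onset ", x$shrink_onset_age, ")\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
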