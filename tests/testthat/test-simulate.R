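test_that("measurement model reproduces the archival rounding conventions", {
  # 170 cm = 66.9291 in -> floored to 66.75 in -> 169.545 cm
  expect_equal(measurement_model(170, 70)$height_cm, 66.75 * 2.54, tolerance = 1e-10)
  # 70 kg = 154.32 lb -> 155 lb -> 70.3068 kg
  expect_equal(measurement_model(170, 70)$weight_kg, 155 * 0.45359237, tolerance = 1e-10)
  # flooring is a fixed point
  h1 <- measurement_model(170, 70)$height_cm
  expect_equal(measurement_model(h1, 70)$height_cm, h1, tolerance = 1e-10)
  # identity when disabled, error on non-positive input
  expect_equal(measurement_model(170.37, 71.2, rounding_enabled = FALSE),
               tibble::tibble(height_cm = 170.37, weight_kg = 71.2))
  expect_error(measurement_model(-1, 70), class = "shrinkbmi_domain_error")
})

test_that("outlier injection hits at the configured rate and never silently drifts", {
  h <- rep(160, 10)
  expect_equal(as.numeric(inject_outliers(h, 0)), h)

  set.seed(5)
  h2 <- inject_outliers(rep(160, 50), 1, c(5, 5))
  expect_true(all(abs(as.numeric(h2) - 160) == 5))
  expect_equal(attr(h2, "n_replaced"), 50)

  set.seed(6)
  big <- inject_outliers(rep(160, 10000), 0.01)
  k <- attr(big, "n_replaced")
  expect_gt(k, qbinom(1e-6, 10000, 0.01))
  expect_lt(k, qbinom(1 - 1e-6, 10000, 0.01))
  moved <- as.numeric(big) != 160
  expect_equal(sum(moved), k)
  expect_true(all(abs(as.numeric(big)[moved] - 160) >= 2.5 &
                    abs(as.numeric(big)[moved] - 160) <= 10))
})

test_that("simulated cohorts are deterministic and schedule-eligible by construction", {
  cfg <- sim_config(n_subjects = 100, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$exams, b$exams)
  expect_identical(a$truth_exams, b$truth_exams)

  per <- dplyr::summarise(dplyr::group_by(a$exams, subject_id),
                          early = any(age <= 40), late = any(age > 40))
  expect_equal(nrow(per), 100)
  expect_true(all(per$early & per$late))
  # ages strictly increasing within subject
  expect_true(all(dplyr::summarise(dplyr::group_by(a$exams, subject_id),
                                   ok = all(diff(age) > 0))$ok))
})

test_that("noise-free recorded values equal latent truth", {
  sim <- simulate_cohort(noise_free_config(n = 30, seed = 3))
  expect_equal(sim$exams$height_cm, sim$truth_exams$true_height, tolerance = 1e-12)
  # weight comes from the young-height BMI trajectory, so the recorded BMI
  # equals the latent BMI exactly while stature is still the young height,
  # and exceeds it once shrinkage sets in
  early <- sim$truth_exams$age <= 40
  expect_equal(sim$exams$bmi[early], sim$truth_exams$true_bmi[early],
               tolerance = 1e-12)
  expect_true(all(sim$exams$bmi[!early] >= sim$truth_exams$true_bmi[!early] - 1e-12))
})

test_that("latent truth respects the height-loss model", {
  sim <- simulate_cohort(sim_config(n_subjects = 200, seed = 8))
  tr <- dplyr::left_join(sim$truth_exams,
                         sim$truth_subjects[c("subject_id", "true_young_height")],
                         by = "subject_id")
  early <- tr$age <= 40
  expect_equal(tr$true_height[early], tr$true_young_height[early], tolerance = 1e-12)
  dec <- dplyr::summarise(dplyr::group_by(tr, subject_id),
                          ok = all(diff(true_height[age > 40]) <= 1e-12))
  expect_true(all(dec$ok))
})

test_that("height-loss and young-BMI marginals match the configured calibration", {
  sim <- simulate_cohort(sim_config(n_subjects = 2200, seed = 31))
  ts <- sim$truth_subjects
  for (s in c("F", "M")) {
    rate <- ts$true_shrink_rate[ts$sex == s]
    expect_gt(length(rate), 1000)
    target <- if (s == "F") 4.8 else 3.6
    expect_lt(abs(mean(rate) * 40 - target), 0.2)
  }
  expect_true(all(ts$true_young_bmi[ts$sex == "F"] >= 17 &
                    ts$true_young_bmi[ts$sex == "F"] <= 35))
  expect_true(all(ts$true_young_bmi[ts$sex == "M"] >= 19 &
                    ts$true_young_bmi[ts$sex == "M"] <= 35))
})

test_that("disease draws reproduce the configured prevalence ratio near age 50", {
  sim <- simulate_cohort(sim_config(n_subjects = 8000, seed = 12))
  tr <- dplyr::left_join(sim$truth_exams, sim$truth_subjects[c("subject_id", "sex")],
                         by = "subject_id")
  win <- dplyr::filter(tr, age >= 48, age <= 52)
  for (s in c("F", "M")) {
    d <- dplyr::filter(win, sex == s)
    ratio <- mean(d$prediabetes[d$true_obese]) / mean(d$prediabetes[!d$true_obese])
    target <- if (s == "F") 2.8 else 2.4
    expect_lt(abs(ratio - target), 0.45)
  }
  # glucose values are drawn consistently with the drawn state
  g <- glycemic_flags(sim$exams$glucose_mgdl)
  expect_equal(g$prediabetes, sim$truth_exams$prediabetes)
  expect_equal(g$diabetes, sim$truth_exams$diabetes)
  # blood pressure / medication consistent with hypertension state
  h <- hypertension_flag(sim$exams$sbp_mmhg, sim$exams$dbp_mmhg, sim$exams$med_flag)
  expect_equal(h, sim$truth_exams$hypertension)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), class = "shrinkbmi_config_error")
  expect_error(sim_config(female_fraction = 1.2), class = "shrinkbmi_config_error")
  expect_error(sim_config(height_noise_sd = -1), class = "shrinkbmi_config_error")
  expect_error(sim_config(shrink_onset_age = 90), class = "shrinkbmi_config_error")
  expect_error(sim_config(young_height_mean_f = Inf), class = "shrinkbmi_config_error")
})

test_that("sim_config round-trips through a YAML file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 25", "female_fraction: 1.0", "seed: 7",
               "shrink_rate_f: 0.15"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_subjects, 25L)
  expect_equal(cfg$shrink_rate_f, 0.15)
  expect_equal(cfg$exam_interval, 2)
  writeLines("not_a_key: 1", path)
  expect_error(read_sim_config(path), class = "shrinkbmi_config_error")
})
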