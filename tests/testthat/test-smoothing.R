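test_that("degree-1 LOWESS reproduces lines and constants exactly", {
  age <- c(31, 33.5, 36, 40, 45, 52, 60, 71)
  line <- 100 - 0.1 * age
  expect_equal(lowess_fit(age, line), line, tolerance = 1e-9)
  expect_equal(lowess_fit(age, rep(7, 8)), rep(7, 8), tolerance = 1e-12)
  expect_error(lowess_fit(age[1:3], line[1:3]), class = "shrinkbmi_too_few_points")
  expect_error(lowess_fit(rev(age), line))
  expect_error(lowess_fit(age, line, frac = 0))
})

test_that("LOWESS agrees with a direct tricube weighted-least-squares oracle", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    age <- sort(runif(n, 30, 80)) + seq_len(n) * 1e-3
    y <- 165 - 0.08 * age + rnorm(n, 0, 0.6)
    frac <- runif(1, 0.4, 1)
    expect_equal(lowess_fit(age, y, frac), lowess_oracle(age, y, frac),
                 tolerance = 1e-8)
  }
  # a spiked point pulls the local fit less than its own magnitude
  age <- seq(40, 58, by = 2)
  y <- 170 - 0.1 * (age - 40)
  y[5] <- y[5] + 5
  fit <- lowess_fit(age, y, frac = 0.6)
  expect_equal(fit, lowess_oracle(age, y, 0.6), tolerance = 1e-8)
  off_spike <- setdiff(seq_along(age), 5)
  expect_true(all(abs(fit[off_spike] - (170 - 0.1 * (age[off_spike] - 40))) < 5))
})

test_that("two-threshold outlier rule matches hand evaluation", {
  # median residual 0.2, 6x = 1.2: only the 2.0 point passes both thresholds
  expect_equal(reject_outliers(c(0.1, 0.1, 0.2, 0.3, 2.0), rep(0, 5), 1),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # 0.9 exceeds 6x the median (0.6) but sits under the 1 cm floor
  expect_equal(reject_outliers(c(0.1, 0.1, 0.1, 0.1, 0.9), rep(0, 5), 1),
               rep(FALSE, 5))
  # all residuals zero: nothing can reach the floor
  expect_equal(reject_outliers(rep(3, 4), rep(3, 4), 1), rep(FALSE, 4))
  # the rule is scale-aware: same shape, BMI floor 0.2
  expect_equal(reject_outliers(c(0.02, 0.02, 0.04, 0.06, 0.4), rep(0, 5), 0.2),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(reject_outliers(1:3, 1:3, 0))
})

test_that("rejection-refit recovers a linear trajectory carrying one spike", {
  age <- seq(40, 58, by = 2)
  truth <- 170 - 0.1 * (age - 40)
  y <- truth
  y[4] <- y[4] + 5
  s <- smooth_with_rejection(age, y, abs_floor = 1)
  expect_true(attr(s, "smoothed"))
  expect_equal(which(s$outlier), 4L)
  expect_equal(s$fitted, truth, tolerance = 0.1)
  # idempotent: rejection applied to the refit flags nothing further
  keep <- !s$outlier
  expect_false(any(reject_outliers(s$raw[keep], s$fitted[keep], 1)))
})

test_that("noise-free linear series pass through untouched; short series fall back", {
  age <- seq(35, 65, by = 3)
  y <- 168 - 0.05 * (age - 35)
  s <- smooth_with_rejection(age, y, abs_floor = 1)
  expect_false(any(s$outlier))
  expect_equal(s$fitted, y, tolerance = 1e-9)

  s3 <- smooth_with_rejection(c(40, 45, 50), c(170, 171, 169), abs_floor = 1)
  expect_false(attr(s3, "smoothed"))
  expect_equal(s3$fitted, s3$raw)
  expect_false(any(s3$outlier))
  expect_error(smooth_with_rejection(numeric(0), numeric(0), 1),
               class = "shrinkbmi_domain_error")
})

test_that("rejection is abandoned when fewer than 4 points would remain", {
  age <- c(40, 42, 44, 46)
  y <- c(170, 170, 170, 190)
  s <- smooth_with_rejection(age, y, abs_floor = 1)
  expect_true(attr(s, "smoothed"))
  expect_false(any(s$outlier))
  expect_equal(s$fitted, lowess_fit(age, y), tolerance = 1e-12)
})

test_that("BMI consistency filter compares recorded vs recomputed BMI at 5 units", {
  # recomputed 70/(1.7^2) = 24.22: recorded 30 differs by 5.78 -> excluded
  expect_false(bmi_consistency_filter(30, 70, 170))
  expect_true(bmi_consistency_filter(24.5, 70, 170))
  expect_true(bmi_consistency_filter(bmi(70, 170), 70, 170))
})

test_that("cohort smoothing flags injected gross errors and reports QC counts", {
  sim <- simulate_cohort(noise_free_config(n = 25, seed = 14))
  exams <- sim$exams
  # corrupt one interior exam of one subject by +8 cm
  i <- which(exams$subject_id == "S0003" & exams$age > 45 & exams$age < 70)[2]
  exams$height_cm[i] <- exams$height_cm[i] + 8
  exams$bmi[i] <- exams$weight_kg[i] / (exams$height_cm[i] / 100)^2
  sm <- smooth_cohort(exams)
  expect_true(sm$height_outlier[sm$subject_id == exams$subject_id[i] &
                                  sm$age == exams$age[i]])
  # fitted value at the corrupted age stays near the latent truth
  truth_i <- sim$truth_exams$true_height[i]
  fit_i <- sm$height_fitted[sm$subject_id == exams$subject_id[i] &
                              sm$age == exams$age[i]]
  expect_lt(abs(fit_i - truth_i), 1)
  qc <- qc_summary(sm)
  expect_equal(nrow(qc), 25)
  # the corrupted subject carries every flag (a noise-free series has a tiny
  # median residual, so the 1 cm floor may also catch points the spike drags)
  expect_gte(sum(qc$n_height_outliers), 1)
  expect_equal(sum(qc$n_height_outliers),
               qc$n_height_outliers[qc$subject_id == exams$subject_id[i]])
  expect_true(all(qc$height_smoothed))
})
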