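CM_PER_IN <- 2.54
KG_PER_LB <- 0.45359237

#' Apply the archival measurement conventions to height and weight
#'
#' Height is converted to inches and floored to the next lower quarter inch;
#' weight is converted to pounds and rounded half-up to the nearest 5 lb.
#' These conventions reproduce the granularity of mid-century clinic records,
#' where oscillation across a rounding threshold creates spurious height
#' changes that the smoothing stage must absorb.
#'
#' @param height_cm,weight_kg Positive numerics (recycled to a common length).
#' @param rounding_enabled If `FALSE`, inputs pass through unchanged.
#' @return A tibble with columns `height_cm` and `weight_kg`.
#' @export
#' @examples
#' measurement_model(170, 70) # 169.545 cm, 70.31 kg
measurement_model <- function(height_cm, weight_kg, rounding_enabled = TRUE) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    rlang::abort("height and weight must be positive", class = "shrinkbmi_domain_error")
  }
  if (rounding_enabled) {
    inches <- height_cm / CM_PER_IN
    height_cm <- floor(inches * 4 + 1e-7) / 4 * CM_PER_IN
    pounds <- weight_kg / KG_PER_LB
    weight_kg <- floor(pounds / 5 + 0.5) * 5 * KG_PER_LB
  }
  tibble::tibble(height_cm = height_cm, weight_kg = weight_kg)
}

#' Inject gross recording errors into a height series
#'
#' Each point is independently replaced, with probability `prob`, by the true
#' value shifted up or down (random sign) by a magnitude drawn uniformly from
#' `magnitude_range`. Emulates the multi-inch "growth or shrinkage" blunders
#' seen in archival height data. Uses the current RNG stream.
#'
#' @param heights Numeric vector (cm).
#' @param prob Per-point replacement probability in `[0, 1]`.
#' @param magnitude_range Two values (cm), the error magnitude range.
#' @return The perturbed vector, with attribute `n_replaced` giving the
#'   number of points altered.
#' @export
inject_outliers <- function(heights, prob, magnitude_range = c(2.5, 10)) {
  stopifnot(prob >= 0, prob <= 1, length(magnitude_range) == 2)
  n <- length(heights)
  hit <- stats::runif(n) < prob
  sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  mag <- stats::runif(n, magnitude_range[1], magnitude_range[2])
  heights[hit] <- heights[hit] + (sign * mag)[hit]
  attr(heights, "n_replaced") <- sum(hit)
  heights
}

# inverse-CDF truncated normal draw; deterministic given the RNG stream
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep_len(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

#' Simulate a synthetic longitudinal cohort with latent truth
#'
#' Generates a long-format exam table with the statistical structure the
#' height-corrected BMI analysis assumes, plus the latent per-subject and
#' per-exam truth used in parameter-recovery tests.
#'
#' Each subject enrolls at a uniform age within `enroll_age_range` and is
#' examined every `exam_interval` years up to `final_age`, so everyone has at
#' least one exam at age 40 or before and at least one after 40. True height
#' is constant at the subject's young-adult height until `shrink_onset_age`,
#' then declines linearly at a subject-specific rate. Weight follows a BMI
#' trajectory (young-adult BMI plus a post-40 drift and exam-to-exam noise)
#' applied to the subject's *true young height*, so the latent obesity state
#' is the young-height BMI at each exam. Recorded height adds measurement
#' noise, occasional gross errors ([inject_outliers()]) and the archival
#' rounding conventions ([measurement_model()]); recorded BMI is computed
#' from the recorded weight and height. Glycemic state (normal /
#' pre-diabetic / diabetic) and hypertension are drawn per exam with
#' prevalences `base(age) * RR^true_obese`, and glucose and blood-pressure
#' values are then drawn consistently with the state, so the configured
#' relative risks hold exactly in expectation.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical cohort.
#' @return An object of class `"cohort_sim"`: a list with
#'   \describe{
#'     \item{exams}{tibble, one row per subject-exam: `subject_id`, `sex`,
#'       `age`, `height_cm`, `weight_kg`, `bmi`, `glucose_mgdl`, `sbp_mmhg`,
#'       `dbp_mmhg`, `med_flag`.}
#'     \item{truth_subjects}{tibble: `subject_id`, `sex`, `true_young_height`,
#'       `true_shrink_rate`, `true_young_bmi`.}
#'     \item{truth_exams}{tibble: `subject_id`, `age`, `true_height`,
#'       `true_bmi`, `true_obese`, `prediabetes`, `diabetes`, `hypertension`.}
#'     \item{config, seed}{the inputs.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 20, seed = 3))
#' dplyr::count(sim$exams, subject_id)[1:3, ]
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  config <- validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$n_subjects

  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  fem <- sex == "F"
  enroll <- stats::runif(n, config$enroll_age_range[1], config$enroll_age_range[2])
  yh <- stats::rnorm(n,
                     ifelse(fem, config$young_height_mean_f, config$young_height_mean_m),
                     config$young_height_sd)
  rate <- rnorm_trunc(n,
                      ifelse(fem, config$shrink_rate_f, config$shrink_rate_m),
                      config$shrink_rate_sd, lower = 0)
  # per-sex truncation bounds for young-adult BMI
  lo <- ifelse(fem, config$young_bmi_range_f[1], config$young_bmi_range_m[1])
  hi <- ifelse(fem, config$young_bmi_range_f[2], config$young_bmi_range_m[2])
  mu <- ifelse(fem, config$young_bmi_mean_f, config$young_bmi_mean_m)
  ybmi <- rnorm_trunc(n, mu, config$young_bmi_sd, lower = lo, upper = hi)

  id <- sprintf("S%04d", seq_len(n))
  n_ex <- floor((config$final_age - enroll) / config$exam_interval) + 1
  idx <- rep(seq_len(n), n_ex)
  k <- sequence(n_ex) - 1
  age <- enroll[idx] + k * config$exam_interval
  N <- length(age)

  onset <- config$shrink_onset_age
  true_height <- yh[idx] - rate[idx] * pmax(age - onset, 0)
  true_bmi <- ybmi[idx] + config$bmi_age_drift * pmax(age - 40, 0) +
    stats::rnorm(N, 0, config$bmi_noise_sd)
  true_weight <- true_bmi * (yh[idx] / 100)^2

  h_meas <- true_height + stats::rnorm(N, 0, config$height_noise_sd)
  h_meas <- as.numeric(inject_outliers(h_meas, config$outlier_prob,
                                       config$outlier_magnitude))
  rec <- measurement_model(h_meas, true_weight, config$rounding_enabled)
  bmi_rec <- rec$weight_kg / (rec$height_cm / 100)^2

  true_obese <- true_bmi >= 30
  rr_pre <- ifelse(fem[idx], config$rr_prediab_f, config$rr_prediab_m)
  rr_dia <- ifelse(fem[idx], config$rr_diab_f, config$rr_diab_m)
  rr_htn <- ifelse(fem[idx], config$rr_htn_f, config$rr_htn_m)
  base_at <- function(coefs) clamp01(coefs[1] + coefs[2] * (age - 40))
  p_dia <- clamp01(base_at(config$diab_base) * rr_dia^true_obese)
  p_pre <- pmin(clamp01(base_at(config$prediab_base) * rr_pre^true_obese), 1 - p_dia)
  u <- stats::runif(N)
  diabetes <- u < p_dia
  prediabetes <- !diabetes & u < p_dia + p_pre
  glucose <- stats::runif(N, 70, 140)
  glucose[prediabetes] <- stats::runif(sum(prediabetes), 140, 200)
  glucose[diabetes] <- stats::runif(sum(diabetes), 200, 300)

  p_htn <- clamp01(base_at(config$htn_base) * rr_htn^true_obese)
  hypertension <- stats::runif(N) < p_htn
  med_flag <- hypertension & stats::runif(N) < config$med_fraction
  controlled <- med_flag & stats::runif(N) < config$controlled_fraction
  elevated <- hypertension & !controlled
  sbp <- stats::runif(N, 100, 139)
  dbp <- stats::runif(N, 60, 89)
  sbp[elevated] <- stats::runif(sum(elevated), 140, 185)
  dbp[elevated] <- stats::runif(sum(elevated), 90, 110)

  exams <- tibble::tibble(
    subject_id = id[idx],
    sex = sex[idx],
    age = age,
    height_cm = rec$height_cm,
    weight_kg = rec$weight_kg,
    bmi = bmi_rec,
    glucose_mgdl = glucose,
    sbp_mmhg = sbp,
    dbp_mmhg = dbp,
    med_flag = med_flag
  )
  truth_subjects <- tibble::tibble(
    subject_id = id, sex = sex,
    true_young_height = yh,
    true_shrink_rate = rate,
    true_young_bmi = ybmi
  )
  truth_exams <- tibble::tibble(
    subject_id = id[idx], age = age,
    true_height = true_height,
    true_bmi = true_bmi,
    true_obese = true_obese,
    prediabetes = prediabetes,
    diabetes = diabetes,
    hypertension = hypertension
  )
  structure(list(exams = exams,
                 truth_subjects = truth_subjects,
                 truth_exams = truth_exams,
                 config = config,
                 seed = as.integer(seed)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", nrow(x$truth_subjects), " subjects, ",
      nrow(x$exams), " exams, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
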