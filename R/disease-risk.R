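#' Glycemic state flags from non-fasting glucose
#'
#' Diabetes is glucose above 200 mg/dL; pre-diabetes is glucose above 140 and
#' at most 200 mg/dL, so the two flags are mutually exclusive.
#'
#' @param glucose_mgdl Non-negative numeric (mg/dL).
#' @return Tibble with logical `prediabetes` and `diabetes`.
#' @export
#' @examples
#' glycemic_flags(c(140, 150, 210))
glycemic_flags <- function(glucose_mgdl) {
  if (any(glucose_mgdl < 0, na.rm = TRUE)) {
    rlang::abort("glucose must be non-negative", class = "shrinkbmi_domain_error")
  }
  tibble::tibble(
    prediabetes = glucose_mgdl > 140 & glucose_mgdl <= 200,
    diabetes = glucose_mgdl > 200
  )
}

#' Hypertension flag
#'
#' Present iff the subject is coded as taking an antihypertensive medication,
#' or systolic pressure is at least 140 mmHg, or diastolic at least 90 mmHg.
#'
#' @param sbp_mmhg,dbp_mmhg Non-negative pressures.
#' @param med_flag Logical medication indicator.
#' @return Logical vector.
#' @export
hypertension_flag <- function(sbp_mmhg, dbp_mmhg, med_flag) {
  if (any(sbp_mmhg < 0 | dbp_mmhg < 0, na.rm = TRUE)) {
    rlang::abort("pressures must be non-negative", class = "shrinkbmi_domain_error")
  }
  med_flag | sbp_mmhg >= 140 | dbp_mmhg >= 90
}

#' Add the three disease flags to an exam or summary table
#'
#' @param df Tibble with `glucose_mgdl`, `sbp_mmhg`, `dbp_mmhg`, `med_flag`.
#' @return `df` with logical columns `prediabetes`, `diabetes`,
#'   `hypertension` appended.
#' @export
disease_flags <- function(df) {
  g <- glycemic_flags(df$glucose_mgdl)
  dplyr::mutate(df,
    prediabetes = g$prediabetes,
    diabetes = g$diabetes,
    hypertension = hypertension_flag(df$sbp_mmhg, df$dbp_mmhg, df$med_flag)
  )
}

#' Relative risk from two exposure strata
#'
#' The disease fraction among the obese divided by the disease fraction among
#' the non-obese. Undefined cases are returned as `NA` rather than infinity:
#' an empty stratum, or zero events among the non-obese. Zero events among
#' the obese with non-zero non-obese events gives 0.
#'
#' @param disease,obese Equal-length logical vectors; pairs with `NA` in
#'   either are dropped.
#' @return One-row tibble: `rr`, `n_obese`, `n_nonobese`, `events_obese`,
#'   `events_nonobese`.
#' @export
#' @examples
#' relative_risk(rep(c(TRUE, FALSE), c(80, 720)),
#'               rep(c(TRUE, FALSE, TRUE, FALSE), c(50, 30, 150, 570)))
relative_risk <- function(disease, obese) {
  if (length(disease) != length(obese)) {
    rlang::abort("disease and obese must have equal length")
  }
  ok <- !is.na(disease) & !is.na(obese)
  disease <- disease[ok]
  obese <- obese[ok]
  n_ob <- sum(obese)
  n_no <- sum(!obese)
  e_ob <- sum(disease & obese)
  e_no <- sum(disease & !obese)
  rr <- if (n_ob == 0 || n_no == 0 || e_no == 0) NA_real_ else (e_ob / n_ob) / (e_no / n_no)
  tibble::tibble(rr = rr, n_obese = n_ob, n_nonobese = n_no,
                 events_obese = e_ob, events_nonobese = e_no)
}

#' Relative risk of disease by age bin, under current or corrected BMI
#'
#' Within each sex and age bin, obesity is defined as the chosen BMI variant
#' at 30 kg/m2 or above; everyone below 30 (overweight included) is the
#' comparison stratum. Each subject contributes one exam per bin (closest to
#' the bin centre); exams with an undefined BMI are dropped. A log-RR Wald
#' 95% interval is attached for plotting.
#'
#' @param summaries Output of [subject_summaries()], with disease flags
#'   (added automatically if absent).
#' @param bmi_mode `"current"` or `"corrected"`.
#' @param disease `"prediabetes"`, `"diabetes"` or `"hypertension"`.
#' @param bin_width Age bin width (years).
#' @return Tibble: `sex`, `age_bin`, `disease`, `bmi_mode`, `rr`, counts,
#'   `rr_lo`, `rr_hi`.
#' @export
rr_by_age <- function(summaries,
                      bmi_mode = c("current", "corrected"),
                      disease = c("prediabetes", "diabetes", "hypertension"),
                      bin_width = 5) {
  bmi_mode <- match.arg(bmi_mode)
  disease <- match.arg(disease)
  if (!all(c("prediabetes", "diabetes", "hypertension") %in% names(summaries))) {
    summaries <- disease_flags(summaries)
  }
  bmi_col <- paste0(bmi_mode, "_bmi")
  df <- summaries |>
    dplyr::filter(!is.na(.data[[bmi_col]])) |>
    dplyr::mutate(obese = .data[[bmi_col]] >= 30) |>
    dedupe_per_bin(bin_width)
  df |>
    dplyr::group_by(.data$sex, .data$age_bin) |>
    dplyr::group_modify(~ relative_risk(.x[[disease]], .x$obese)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      disease = disease,
      bmi_mode = bmi_mode,
      se_log = sqrt(1 / .data$events_obese - 1 / .data$n_obese +
                      1 / .data$events_nonobese - 1 / .data$n_nonobese),
      rr_lo = exp(log(.data$rr) - 1.96 * .data$se_log),
      rr_hi = exp(log(.data$rr) + 1.96 * .data$se_log)
    ) |>
    dplyr::select(dplyr::all_of(c("sex", "age_bin", "disease", "bmi_mode", "rr",
                                  "n_obese", "n_nonobese", "events_obese",
                                  "events_nonobese", "rr_lo", "rr_hi")))
}

#' All relative-risk curves (three diseases, both BMI definitions)
#'
#' @inheritParams rr_by_age
#' @return Row-bound [rr_by_age()] output over every disease and BMI mode.
#' @export
rr_curves <- function(summaries, bin_width = 5) {
  if (!all(c("prediabetes", "diabetes", "hypertension") %in% names(summaries))) {
    summaries <- disease_flags(summaries)
  }
  combos <- tidyr::expand_grid(
    disease = c("prediabetes", "diabetes", "hypertension"),
    bmi_mode = c("current", "corrected")
  )
  purrr::pmap(combos, function(disease, bmi_mode) {
    rr_by_age(summaries, bmi_mode = bmi_mode, disease = disease,
              bin_width = bin_width)
  }) |>
    dplyr::bind_rows()
}
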