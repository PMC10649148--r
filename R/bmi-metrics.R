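#' Body mass index
#'
#' The Quetelet index: weight in kilograms over squared height in metres.
#'
#' @param weight_kg,height_cm Positive numerics.
#' @return BMI in kg/m2.
#' @export
#' @examples
#' bmi(70, 175) # 22.86
bmi <- function(weight_kg, height_cm) {
  if (any(height_cm <= 0, na.rm = TRUE)) {
    rlang::abort("height must be positive", class = "shrinkbmi_domain_error")
  }
  weight_kg / (height_cm / 100)^2
}

#' Subjects usable for the young-height construction
#'
#' A subject is eligible iff they have at least one exam at age 40 or before
#' and at least one after age 40 — i.e. their own young height and their own
#' later stature are both observed, so each subject is compared with
#' themselves.
#'
#' @param exams Exam tibble with `subject_id` and `age`.
#' @return Character vector of eligible subject ids.
#' @export
eligible_subjects <- function(exams) {
  exams |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = any(.data$age <= 40) && any(.data$age > 40)) |>
    dplyr::filter(.data$ok) |>
    dplyr::pull(.data$subject_id)
}

# mean of (smoothed when available) heights at ages <= 40, flagged points
# excluded; falls back to all <=40 fitted values if every one is flagged
young_height_values <- function(age, height_raw, height_fitted,
                                height_outlier, height_smoothed) {
  vals <- if (isTRUE(height_smoothed[1])) height_fitted else height_raw
  early <- age <= 40
  use <- early & !height_outlier
  if (!any(use)) use <- early
  if (!any(use)) {
    rlang::abort("subject has no height measurement at age <= 40",
                 class = "shrinkbmi_ineligible")
  }
  vals[use]
}

#' Young height of one smoothed series
#'
#' Arithmetic mean of the height values at ages 40 and under — smoothed
#' fitted values when the series was smoothed (>= 4 points), raw values
#' otherwise — excluding points flagged by the outlier rule.
#'
#' @param series A `smoothed_series` from [smooth_with_rejection()].
#' @return Young height in cm.
#' @export
young_height <- function(series) {
  mean(young_height_values(series$age, series$raw, series$fitted,
                           series$outlier, attr(series, "smoothed")))
}

#' Height lost since young adulthood
#'
#' @param young_height,current_height Heights in cm.
#' @return Shrinkage in cm; may be slightly negative under measurement noise
#'   and is reported as-is, not clipped.
#' @export
shrinkage <- function(young_height, current_height) {
  if (any(young_height <= 0 | current_height <= 0, na.rm = TRUE)) {
    rlang::abort("heights must be positive", class = "shrinkbmi_domain_error")
  }
  young_height - current_height
}

#' Per-exam subject summaries: young height, shrinkage and the three BMIs
#'
#' Restricts to eligible subjects ([eligible_subjects()]) and computes, for
#' every exam: the subject's young height; the current height (smoothed
#' fitted value when available); shrinkage; the current BMI (the smoothed BMI
#' series, `NA` where the consistency filter excluded the exam); the
#' corrected BMI, i.e. the recorded weight over the squared young height; and
#' the excess BMI, current minus corrected — the BMI inflation attributable
#' to height loss alone.
#'
#' @param smoothed Output of [smooth_cohort()].
#' @return Tibble, one row per eligible subject-exam, carrying the clinical
#'   columns (`glucose_mgdl`, `sbp_mmhg`, `dbp_mmhg`, `med_flag`) through for
#'   downstream risk analysis.
#' @export
subject_summaries <- function(smoothed) {
  keep_ids <- eligible_subjects(smoothed)
  smoothed |>
    dplyr::filter(.data$subject_id %in% keep_ids) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      young_height = mean(young_height_values(
        .data$age, .data$height_cm, .data$height_fitted,
        .data$height_outlier, .data$height_smoothed))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      current_height = ifelse(.data$height_smoothed, .data$height_fitted, .data$height_cm),
      shrinkage = .data$young_height - .data$current_height,
      current_bmi = .data$bmi_fitted,
      corrected_bmi = bmi(.data$weight_kg, .data$young_height),
      excess_bmi = .data$current_bmi - .data$corrected_bmi
    ) |>
    dplyr::select(dplyr::all_of(c(
      "subject_id", "sex", "age", "young_height", "current_height",
      "shrinkage", "weight_kg", "current_bmi", "corrected_bmi", "excess_bmi",
      "glucose_mgdl", "sbp_mmhg", "dbp_mmhg", "med_flag"
    )))
}
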