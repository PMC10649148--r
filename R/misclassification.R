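#' WHO-style BMI category
#'
#' `< 25` is below overweight (normal or underweight pooled), `[25, 30)` is
#' overweight, `>= 30` is obese.
#'
#' @param bmi Positive numeric.
#' @return Factor with levels `under_normal`, `overweight`, `obese`.
#' @export
categorize_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
      labels = c("under_normal", "overweight", "obese"))
}

#' Label a subject-exam by current and corrected BMI category
#'
#' "Wrong obese" means currently obese (current BMI >= 30) but below the
#' obesity cutoff once the BMI is corrected to young height; "wrong
#' overweight" means currently overweight (`[25, 30)`) but below 25 when
#' corrected. The two flags are mutually exclusive by construction.
#'
#' @param current_bmi,corrected_bmi Numeric vectors (kg/m2).
#' @return Tibble with `current_category`, `corrected_category`,
#'   `wrong_overweight`, `wrong_obese`.
#' @export
#' @examples
#' classify_bmi(c(31, 26, 31), c(28.5, 24.2, 30.2))
classify_bmi <- function(current_bmi, corrected_bmi) {
  cur <- categorize_bmi(current_bmi)
  cor <- categorize_bmi(corrected_bmi)
  tibble::tibble(
    current_category = cur,
    corrected_category = cor,
    wrong_overweight = !is.na(cur) & !is.na(cor) &
      cur == "overweight" & corrected_bmi < 25,
    wrong_obese = !is.na(cur) & !is.na(cor) &
      cur == "obese" & corrected_bmi < 30
  )
}

#' Assign ages to bins centred on multiples of the bin width
#'
#' With the default width 5, bin "80" covers ages `[77.5, 82.5)`.
#'
#' @param age Numeric ages.
#' @param bin_width Bin width in years.
#' @return Numeric bin centres.
#' @export
assign_age_bin <- function(age, bin_width = 5) {
  bin_width * floor(age / bin_width + 0.5)
}

# one exam per subject per (sex, bin): the one closest to the bin centre,
# ties resolved toward the younger exam
dedupe_per_bin <- function(df, bin_width) {
  df |>
    dplyr::mutate(age_bin = assign_age_bin(.data$age, bin_width)) |>
    dplyr::group_by(.data$subject_id, .data$age_bin) |>
    dplyr::arrange(abs(.data$age - .data$age_bin), .data$age, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Age-resolved misclassification curves
#'
#' For every sex and age bin, the fraction of subject-exams flagged wrong
#' overweight or wrong obese, under two denominators: `population` (all exams
#' of that sex in the bin) and `category` (only exams currently in the
#' category in question). Each subject contributes at most one exam per bin
#' (the one closest to the bin centre). Exams where either BMI is undefined
#' (consistency-filter exclusions) are dropped.
#'
#' @param summaries Output of [subject_summaries()].
#' @param bin_width Age bin width in years (bins centred on its multiples).
#' @return Tidy tibble: `sex`, `age_bin`, `category` (`overweight`/`obese`),
#'   `denominator` (`population`/`category`), `n_wrong`, `n_denom`,
#'   `fraction`. `fraction` is `NA` (not 0) where the denominator is empty.
#' @export
misclassification_curve <- function(summaries, bin_width = 5) {
  labelled <- summaries |>
    dplyr::filter(!is.na(.data$current_bmi), !is.na(.data$corrected_bmi))
  labelled <- labelled |>
    dplyr::bind_cols(classify_bmi(labelled$current_bmi, labelled$corrected_bmi)) |>
    dedupe_per_bin(bin_width)

  counts <- labelled |>
    dplyr::group_by(.data$sex, .data$age_bin) |>
    dplyr::summarise(
      n_population = dplyr::n(),
      n_cat_overweight = sum(.data$current_category == "overweight"),
      n_cat_obese = sum(.data$current_category == "obese"),
      wrong_overweight = sum(.data$wrong_overweight),
      wrong_obese = sum(.data$wrong_obese),
      .groups = "drop"
    )

  grid <- tidyr::expand_grid(category = c("overweight", "obese"),
                             denominator = c("population", "category"))
  counts |>
    dplyr::cross_join(grid) |>
    dplyr::mutate(
      n_wrong = ifelse(.data$category == "overweight",
                       .data$wrong_overweight, .data$wrong_obese),
      n_denom = dplyr::case_when(
        denominator == "population" ~ n_population,
        category == "overweight" ~ n_cat_overweight,
        TRUE ~ n_cat_obese
      ),
      fraction = ifelse(.data$n_denom > 0, .data$n_wrong / .data$n_denom, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(c("sex", "age_bin", "category", "denominator",
                                  "n_wrong", "n_denom", "fraction"))) |>
    dplyr::arrange(.data$sex, .data$age_bin, .data$category, .data$denominator)
}

#' Misclassification fraction for one sex, bin and category
#'
#' Scalar convenience wrapper around [misclassification_curve()].
#'
#' @inheritParams misclassification_curve
#' @param sex `"F"` or `"M"`.
#' @param age_bin Bin centre (years).
#' @param category `"overweight"` or `"obese"`.
#' @param denominator `"population"` (all exams of that sex in the bin) or
#'   `"category"` (exams currently in the category).
#' @return One-row tibble with `fraction`, `n_wrong`, `n_denom`. Errors if
#'   the bin holds no exams for that sex; returns `fraction = NA` if the bin
#'   exists but the category denominator is empty.
#' @export
misclassification_fraction <- function(summaries, sex, age_bin,
                                       category = c("overweight", "obese"),
                                       denominator = c("population", "category"),
                                       bin_width = 5) {
  category <- match.arg(category)
  denominator <- match.arg(denominator)
  curve <- misclassification_curve(summaries, bin_width)
  row <- curve[curve$sex == sex & curve$age_bin == age_bin &
                 curve$category == category & curve$denominator == denominator, ]
  if (nrow(row) == 0) {
    rlang::abort(sprintf("no exams for sex %s in age bin %s", sex, age_bin),
                 class = "shrinkbmi_empty_bin")
  }
  row[, c("fraction", "n_wrong", "n_denom")]
}
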