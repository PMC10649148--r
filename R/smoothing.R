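#' LOWESS fit of a per-subject trajectory
#'
#' Locally weighted (tricube) degree-1 regression of `values` on `ages`,
#' evaluated at every observation age, with no robustness iterations —
#' robustness against gross errors is supplied downstream by the explicit
#' two-threshold rejection rule ([reject_outliers()]) rather than by
#' iterative reweighting. A globally linear input is reproduced exactly.
#'
#' @param ages Strictly increasing numeric vector (years), length >= 4.
#' @param values Numeric vector, same length.
#' @param frac Smoothing span: fraction of the points in each local window.
#' @return Numeric vector of fitted values at `ages`.
#' @export
lowess_fit <- function(ages, values, frac = 0.6) {
  n <- length(ages)
  if (n < 4) {
    rlang::abort("LOWESS needs at least 4 points", class = "shrinkbmi_too_few_points")
  }
  if (length(values) != n) rlang::abort("ages and values must have equal length")
  if (any(diff(ages) <= 0)) rlang::abort("ages must be strictly increasing")
  if (!(frac > 0 && frac <= 1)) rlang::abort("frac must lie in (0, 1]")
  stats::lowess(ages, values, f = frac, iter = 0, delta = 0)$y
}

#' Two-threshold outlier rule on smoothing residuals
#'
#' A point is flagged iff its absolute residual from the smoothed curve is
#' both more than six times the subject's median absolute residual *and* at
#' least `abs_floor` (1 cm for height, 0.2 kg/m2 for BMI). The multiplicative
#' rule adapts to each subject's own measurement scatter; the absolute floor
#' stops it from flagging the trivial oscillation produced by quarter-inch
#' rounding in subjects with near-zero residuals.
#'
#' @param raw,fitted Equal-length numeric vectors.
#' @param abs_floor Positive absolute residual floor, same units as `raw`.
#' @return Logical vector of outlier flags.
#' @export
#' @examples
#' reject_outliers(c(0.1, 0.1, 0.2, 0.3, 2), rep(0, 5), abs_floor = 1)
reject_outliers <- function(raw, fitted, abs_floor) {
  if (length(raw) != length(fitted)) rlang::abort("raw and fitted must have equal length")
  if (!(abs_floor > 0)) rlang::abort("abs_floor must be positive")
  res <- abs(raw - fitted)
  res > 6 * stats::median(res) & res >= abs_floor
}

# linear interpolation with linear (not constant) extrapolation at the ends
interp_linear <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  n <- length(x)
  if (n >= 2) {
    lo <- xout < x[1]
    hi <- xout > x[n]
    if (any(lo)) {
      s <- (y[2] - y[1]) / (x[2] - x[1])
      out[lo] <- y[1] + s * (xout[lo] - x[1])
    }
    if (any(hi)) {
      s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      out[hi] <- y[n] + s * (xout[hi] - x[n])
    }
  }
  out
}

#' Smooth one trajectory with one rejection--refit cycle
#'
#' For series with at least 4 points: fit LOWESS, flag outliers with
#' [reject_outliers()], refit once on the retained points, and evaluate the
#' refit at *all* original ages (flagged ages get interpolated fitted values
#' so downstream per-age metrics stay defined). If fewer than 4 points would
#' remain after rejection, rejection is abandoned: flags are cleared and the
#' first fit is kept. Series with fewer than 4 points cannot be smoothed and
#' are passed through (`fitted = raw`, no flags, `smoothed = FALSE`).
#'
#' @param ages Strictly increasing ages (years), length >= 1.
#' @param values Numeric vector, same length.
#' @param abs_floor Absolute residual floor for the rejection rule.
#' @param frac LOWESS span.
#' @return A `smoothed_series` tibble with columns `age`, `raw`, `fitted`,
#'   `outlier`, and attribute `smoothed` (scalar logical).
#' @export
smooth_with_rejection <- function(ages, values, abs_floor, frac = 0.6) {
  n <- length(ages)
  if (n == 0) rlang::abort("empty series", class = "shrinkbmi_domain_error")
  if (length(values) != n) rlang::abort("ages and values must have equal length")
  if (n < 4) {
    return(new_smoothed_series(ages, values, values, rep(FALSE, n), smoothed = FALSE))
  }
  fit1 <- lowess_fit(ages, values, frac)
  flags <- reject_outliers(values, fit1, abs_floor)
  if (any(flags) && sum(!flags) >= 4) {
    keep <- !flags
    fit2 <- lowess_fit(ages[keep], values[keep], frac)
    fitted <- interp_linear(ages[keep], fit2, ages)
  } else {
    flags <- rep(FALSE, n)
    fitted <- fit1
  }
  new_smoothed_series(ages, values, fitted, flags, smoothed = TRUE)
}

new_smoothed_series <- function(ages, raw, fitted, outlier, smoothed) {
  tibble::new_tibble(
    list(age = as.numeric(ages), raw = as.numeric(raw),
         fitted = as.numeric(fitted), outlier = outlier),
    nrow = length(ages), smoothed = smoothed, class = "smoothed_series"
  )
}

#' Is a recorded BMI consistent with the recorded weight and height?
#'
#' Keeps a record iff the recorded BMI and the BMI recomputed from weight and
#' height (the smoothed height, when the caller has one) differ by less than
#' 5 kg/m2. Larger discrepancies indicate a transcription error in one of the
#' three fields and the BMI at that exam is excluded from analysis.
#'
#' @param bmi_recorded Recorded BMI (kg/m2).
#' @param weight_kg,height_cm Recorded weight and (preferably smoothed) height.
#' @return Logical keep flags.
#' @export
bmi_consistency_filter <- function(bmi_recorded, weight_kg, height_cm) {
  abs(bmi_recorded - bmi(weight_kg, height_cm)) < 5
}

#' Smooth every subject's height and BMI trajectory
#'
#' Runs [smooth_with_rejection()] per subject, height first (floor
#' `height_floor` cm). The BMI-consistency check then uses the smoothed
#' height where available (raw height otherwise); exams failing it are
#' excluded from the BMI series, and the retained BMI values are smoothed
#' with floor `bmi_floor` kg/m2.
#'
#' @param exams Long-format exam tibble (see [simulate_cohort()] /
#'   [read_cohort()]); rows must be unique in (`subject_id`, `age`).
#' @param frac LOWESS span for both series.
#' @param height_floor,bmi_floor Absolute residual floors for the rejection
#'   rule on the height and BMI series.
#' @return The exam tibble with added columns `height_fitted`,
#'   `height_outlier`, `height_smoothed`, `bmi_kept` (consistency filter),
#'   `bmi_fitted` (`NA` at excluded exams), `bmi_outlier`, `bmi_smoothed`.
#' @export
smooth_cohort <- function(exams, frac = 0.6, height_floor = 1, bmi_floor = 0.2) {
  exams |>
    dplyr::arrange(.data$subject_id, .data$age) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ smooth_one_subject(.x, frac, height_floor, bmi_floor)) |>
    dplyr::ungroup()
}

smooth_one_subject <- function(df, frac, height_floor, bmi_floor) {
  hs <- smooth_with_rejection(df$age, df$height_cm, height_floor, frac)
  h_sm <- attr(hs, "smoothed")
  href <- if (h_sm) hs$fitted else df$height_cm
  keep <- bmi_consistency_filter(df$bmi, df$weight_kg, href)

  bmi_fitted <- rep(NA_real_, nrow(df))
  bmi_outlier <- rep(FALSE, nrow(df))
  b_sm <- FALSE
  if (any(keep)) {
    bs <- smooth_with_rejection(df$age[keep], df$bmi[keep], bmi_floor, frac)
    bmi_fitted[keep] <- bs$fitted
    bmi_outlier[keep] <- bs$outlier
    b_sm <- attr(bs, "smoothed")
  }
  dplyr::mutate(df,
    height_fitted = hs$fitted,
    height_outlier = hs$outlier,
    height_smoothed = h_sm,
    bmi_kept = keep,
    bmi_fitted = bmi_fitted,
    bmi_outlier = bmi_outlier,
    bmi_smoothed = b_sm
  )
}

#' Per-subject smoothing QC counts
#'
#' @param smoothed Output of [smooth_cohort()].
#' @return Tibble with one row per subject: exam count, smoothing status,
#'   number of flagged height and BMI outliers, number of BMI exclusions.
#' @export
qc_summary <- function(smoothed) {
  smoothed |>
    dplyr::group_by(.data$subject_id, .data$sex) |>
    dplyr::summarise(
      n_exams = dplyr::n(),
      height_smoothed = .data$height_smoothed[1],
      n_height_outliers = sum(.data$height_outlier),
      n_bmi_excluded = sum(!.data$bmi_kept),
      n_bmi_outliers = sum(.data$bmi_outlier),
      .groups = "drop"
    )
}
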