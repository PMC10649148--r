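#' Fit a population trend polynomial
#'
#' Pooled ordinary-least-squares polynomial fit of a response over age,
#' expressed in years past a reference age. For height loss the convention is
#' shrinkage (cm) versus years after age 35: exams at ages below the
#' reference are not part of the predictor's domain and are dropped, while
#' pre-onset exams at or above it contribute their (near-zero) shrinkage, the
#' intercept absorbing the offset.
#'
#' @param data Tibble containing `age` and the response column.
#' @param degree Polynomial degree, 1 (linear) or 2 (quadratic).
#' @param ref_age Reference age in years; predictor is `age - ref_age`.
#' @param response Name of the response column (default `"shrinkage"`).
#' @return A `trend_fit` object wrapping the `lm` fit with its metadata.
#'   Supports [predict()][predict.trend_fit()], [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' d <- tibble::tibble(age = 45:80, shrinkage = 0.12 * (45:80 - 40))
#' coef(fit_trend(d)$model)[2] # slope 0.12
fit_trend <- function(data, degree = 1, ref_age = 35, response = "shrinkage") {
  if (!degree %in% c(1, 2)) rlang::abort("degree must be 1 or 2")
  if (!response %in% names(data)) {
    rlang::abort(paste0("column '", response, "' not found"))
  }
  df <- data |>
    dplyr::filter(.data$age >= ref_age, !is.na(.data[[response]])) |>
    dplyr::transmute(x = .data$age - ref_age, y = .data[[response]])
  if (nrow(df) <= degree + 1) {
    rlang::abort("too few points for the requested degree",
                 class = "shrinkbmi_domain_error")
  }
  if (length(unique(df$x)) <= degree) {
    rlang::abort("rank-deficient design: not enough distinct ages",
                 class = "shrinkbmi_domain_error")
  }
  model <- stats::lm(y ~ poly(x, degree, raw = TRUE), data = df)
  structure(
    list(model = model, degree = degree, ref_age = ref_age,
         response = response, n = nrow(df),
         coefficients = stats::setNames(
           as.numeric(stats::coef(model)),
           c("intercept", "slope", if (degree == 2) "curvature")),
         sigma2 = suppressWarnings(summary(model))$sigma^2),
    class = "trend_fit"
  )
}

#' Predict a trend fit at given ages
#'
#' @param object A `trend_fit`.
#' @param age Ages (years) at which to evaluate the polynomial.
#' @param ... Unused.
#' @return Numeric predictions in the response units.
#' @export
predict.trend_fit <- function(object, age, ...) {
  x <- age - object$ref_age
  co <- object$coefficients
  out <- co[["intercept"]] + co[["slope"]] * x
  if (object$degree == 2) out <- out + co[["curvature"]] * x^2
  unname(out)
}

#' Total predicted height loss between ages 40 and 80
#'
#' Evaluates the fitted shrinkage polynomial at ages 80 and 40 and returns
#' the difference — the summary statistic by which the population height-loss
#' trend is reported (e.g. a linear rate of 0.12 cm/yr gives 4.8 cm).
#'
#' @param fit A `trend_fit` of shrinkage versus age.
#' @return Loss in cm.
#' @export
total_loss_40_80 <- function(fit) {
  predict(fit, 80) - predict(fit, 40)
}

#' Linear trend of excess BMI
#'
#' Degree-1 OLS of excess BMI against age (default) or against shrinkage,
#' pooled over eligible subject-exams.
#'
#' @param summaries Output of [subject_summaries()].
#' @param predictor `"age"` or `"shrinkage"`.
#' @return A `trend_fit`. For `predictor = "shrinkage"` the stored `ref_age`
#'   is 0 and [predict.trend_fit()] takes shrinkage values in cm.
#' @export
fit_excess_bmi_trend <- function(summaries, predictor = c("age", "shrinkage")) {
  predictor <- match.arg(predictor)
  df <- dplyr::filter(summaries, !is.na(.data$excess_bmi))
  if (predictor == "age") {
    fit <- fit_trend(df, degree = 1, ref_age = 0, response = "excess_bmi")
  } else {
    df2 <- dplyr::transmute(df, age = .data$shrinkage, excess_bmi = .data$excess_bmi)
    fit <- fit_trend(df2, degree = 1, ref_age = 0, response = "excess_bmi")
  }
  fit$predictor <- predictor
  fit
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> ", x$response, " ~ poly(age - ", x$ref_age, ", ",
      x$degree, "), n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' One-row summary of a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble: `r.squared`, `sigma`, `n`, `degree`, `ref_age`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n = x$n,
    degree = x$degree,
    ref_age = x$ref_age
  )
}
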