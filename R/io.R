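COHORT_COLS <- c("subject_id", "sex", "age", "height_cm", "weight_kg", "bmi",
                 "glucose_mgdl", "sbp_mmhg", "dbp_mmhg", "med_flag")

#' Read a long-format cohort CSV
#'
#' Expects one row per subject-exam with the header
#' `subject_id,sex,age,height_cm,weight_kg,bmi,glucose_mgdl,sbp_mmhg,dbp_mmhg,med_flag`.
#' Validation failures are hard errors that name the offenders: missing
#' columns, non-numeric fields (with CSV line numbers), duplicate
#' `(subject_id, age)` pairs, and non-positive heights or weights.
#'
#' @param path CSV file path.
#' @return A typed exam tibble sorted by subject and age.
#' @export
read_cohort <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(COHORT_COLS, header)
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort file is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "shrinkbmi_load_error")
  }
  exams <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    height_cm = readr::col_double(),
    weight_kg = readr::col_double(),
    bmi = readr::col_double(),
    glucose_mgdl = readr::col_double(),
    sbp_mmhg = readr::col_double(),
    dbp_mmhg = readr::col_double(),
    med_flag = readr::col_logical()
  ), show_col_types = FALSE))
  probs <- readr::problems(exams)
  if (nrow(probs) > 0) {
    rlang::abort(paste0("malformed field(s) at line(s): ",
                        paste(unique(probs$row + 1), collapse = ", ")),
                 class = "shrinkbmi_load_error")
  }
  dup <- exams |>
    dplyr::count(.data$subject_id, .data$age) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    pairs <- paste0("(", dup$subject_id, ", ", dup$age, ")")
    rlang::abort(paste0("duplicate (subject_id, age) row(s): ",
                        paste(pairs, collapse = "; ")),
                 class = "shrinkbmi_load_error")
  }
  bad <- which(exams$height_cm <= 0 | exams$weight_kg <= 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("non-positive height/weight at data row(s): ",
                        paste(bad, collapse = ", ")),
                 class = "shrinkbmi_load_error")
  }
  dplyr::arrange(exams, .data$subject_id, .data$age)
}

#' Write an exam table (or simulated cohort) to CSV
#'
#' @param x An exam tibble or a `cohort_sim`; for the latter the truth tables
#'   are written alongside as `<stem>_truth_subjects.csv` /
#'   `<stem>_truth_exams.csv`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  if (inherits(x, "cohort_sim")) {
    stem <- sub("\\.csv$", "", path)
    readr::write_csv(x$exams, path)
    readr::write_csv(x$truth_subjects, paste0(stem, "_truth_subjects.csv"))
    readr::write_csv(x$truth_exams, paste0(stem, "_truth_exams.csv"))
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Run the full height-corrected BMI pipeline
#'
#' Orchestrates the whole analysis: (optionally) simulate a cohort, smooth
#' every subject's height and BMI trajectory, build the subject summaries
#' (young height, shrinkage, current/corrected/excess BMI), and compute the
#' misclassification curves, the relative-risk curves for pre-diabetes,
#' diabetes and hypertension under both BMI definitions, and the population
#' trend fits (linear and quadratic shrinkage per sex; linear excess BMI per
#' sex). With `outdir` set, all tables are written as CSV, the fits and the
#' run manifest as JSON, and the five standard figures as PNG.
#'
#' @param exams Exam tibble (e.g. from [read_cohort()]); if `NULL`, a cohort
#'   is simulated from `config`.
#' @param config A [sim_config()]; used only when `exams` is `NULL`.
#' @param seed Seed for the simulation (default `config$seed`).
#' @param frac LOWESS span.
#' @param bin_width Age bin width for the curve modules.
#' @param outdir Optional output directory.
#' @return A `bmi_pipeline` list: `exams`, `smoothed`, `summaries`, `qc`,
#'   `misclassification`, `relative_risk`, `trends` (named list of
#'   `trend_fit`s), `truth` (when simulated), and `manifest`.
#' @export
run_pipeline <- function(exams = NULL, config = sim_config(),
                         seed = config$seed, frac = 0.6, bin_width = 5,
                         outdir = NULL) {
  truth <- NULL
  if (is.null(exams)) {
    sim <- simulate_cohort(config, seed)
    exams <- sim$exams
    truth <- list(subjects = sim$truth_subjects, exams = sim$truth_exams)
  }
  smoothed <- smooth_cohort(exams, frac = frac)
  summaries <- disease_flags(subject_summaries(smoothed))
  qc <- qc_summary(smoothed)
  mis <- misclassification_curve(summaries, bin_width)
  rr <- rr_curves(summaries, bin_width)

  trends <- list()
  for (s in unique(summaries$sex)) {
    sub <- dplyr::filter(summaries, .data$sex == s)
    trends[[paste0("shrinkage_linear_", s)]] <- fit_trend(sub, degree = 1)
    trends[[paste0("shrinkage_quadratic_", s)]] <- fit_trend(sub, degree = 2)
    trends[[paste0("excess_bmi_", s)]] <- fit_excess_bmi_trend(sub)
  }

  manifest <- list(
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    frac = frac,
    bin_width = bin_width,
    n_subjects = dplyr::n_distinct(exams$subject_id),
    n_exams = nrow(exams),
    n_eligible = length(eligible_subjects(exams)),
    n_height_outliers = sum(smoothed$height_outlier),
    n_bmi_excluded = sum(!smoothed$bmi_kept),
    n_bmi_outliers = sum(smoothed$bmi_outlier)
  )

  out <- structure(list(exams = exams, smoothed = smoothed,
                        summaries = summaries, qc = qc,
                        misclassification = mis, relative_risk = rr,
                        trends = trends, truth = truth, manifest = manifest),
                   class = "bmi_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$exams, file.path(outdir, "exams.csv"))
  readr::write_csv(result$summaries, file.path(outdir, "subject_summaries.csv"))
  readr::write_csv(result$qc, file.path(outdir, "qc.csv"))
  readr::write_csv(result$misclassification, file.path(outdir, "misclassification.csv"))
  readr::write_csv(result$relative_risk, file.path(outdir, "relative_risk.csv"))
  fits <- lapply(result$trends, function(f) {
    list(response = f$response, degree = f$degree, ref_age = f$ref_age,
         n = f$n, coefficients = as.list(f$coefficients))
  })
  jsonlite::write_json(fits, file.path(outdir, "trend_fits.json"), auto_unbox = TRUE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  figs <- pipeline_figures(result)
  for (nm in names(figs)) {
    ggplot2::ggsave(file.path(outdir, paste0(nm, ".png")), figs[[nm]],
                    width = 8, height = 5, dpi = 120)
  }
  invisible(outdir)
}

#' @export
print.bmi_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<bmi_pipeline> ", m$n_subjects, " subjects / ", m$n_exams, " exams (",
      m$n_eligible, " eligible)\n", sep = "")
  cat("  height outliers flagged: ", m$n_height_outliers,
      "; BMI exams excluded: ", m$n_bmi_excluded, "\n", sep = "")
  for (nm in grep("^shrinkage_linear", names(x$trends), value = TRUE)) {
    cat("  ", nm, ": loss 40-80 = ",
        round(total_loss_40_80(x$trends[[nm]]), 2), " cm\n", sep = "")
  }
  invisible(x)
}
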