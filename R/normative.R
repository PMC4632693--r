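#' Fit the healthy-control age-normative model
#'
#' Ordinary least squares of relative putamen volume (RPV, percent of
#' ICV) on age in a healthy-control sample:
#' `RPV_HC(Age) = intercept + slope * Age`. The fitted line is the
#' age-dependent predictor of the RPV expected for a healthy person of a
#' given age; the mean of the fitting sample's observed RPVs is stored
#' as the denominator used when deviations are expressed in percent.
#'
#' @param hc_ages ages in years, n >= 3 (n = 2 fits the interpolating
#'   line with `residual_sd` reported as 0 and flagged undefined).
#' @param hc_rpvs RPV values, percent of ICV.
#' @return An object of class `normative_model`: list with `intercept`,
#'   `slope`, `n_hc`, `residual_sd` (n-2 denominator),
#'   `residual_sd_defined`, `mean_rpv_hc`, `mean_age`, `age_range_fit`.
#' @export
fit_normative <- function(hc_ages, hc_rpvs) {
  stopifnot(length(hc_ages) == length(hc_rpvs))
  n <- length(hc_ages)
  if (n < 2L) stop("need at least 2 control observations", call. = FALSE)
  if (stats::var(hc_ages) == 0) {
    stop("degenerate fit: control ages are all equal", call. = FALSE)
  }
  fit <- stats::lm(hc_rpvs ~ hc_ages)
  co <- stats::coef(fit)
  structure(list(
    intercept = unname(co[1L]),
    slope = unname(co[2L]),
    n_hc = n,
    residual_sd = if (n > 2L) stats::sigma(fit) else 0,
    residual_sd_defined = n > 2L,
    mean_rpv_hc = mean(hc_rpvs),
    mean_age = mean(hc_ages),
    age_range_fit = range(hc_ages)
  ), class = "normative_model")
}

#' Predict the age-expected RPV from a normative model
#'
#' Evaluates `intercept + slope * age`. Ages outside the range of the
#' fitting sample are extrapolations and are flagged in the
#' `"extrapolated"` attribute of the result.
#'
#' @param model a [fit_normative()] model.
#' @param age ages in years, positive (vectorized).
#' @return Expected RPV in percent of ICV, with a logical
#'   `"extrapolated"` attribute of the same length.
#' @export
predict_rpv <- function(model, age) {
  stopifnot(inherits(model, "normative_model"))
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  out <- model$intercept + model$slope * age
  attr(out, "extrapolated") <-
    age < model$age_range_fit[1L] | age > model$age_range_fit[2L]
  out
}

#' Score one patient's age-corrected volumetric deviation
#'
#' The deviation `delta_rpv = RPV_observed - RPV_expected(age)` is in
#' percentage points of ICV; `delta_rpv_percent` expresses it as a
#' percent of the mean control RPV. Negative values indicate atrophy
#' beyond normal aging.
#'
#' @param model a [fit_normative()] model.
#' @param age age in years.
#' @param rpv_ms observed RPV, percent of ICV.
#' @return A one-row data frame: `expected_rpv`, `delta_rpv`,
#'   `delta_rpv_percent`, `extrapolation_flag`.
#' @export
score_patient <- function(model, age, rpv_ms) {
  expected <- predict_rpv(model, age)
  delta <- rpv_ms - as.numeric(expected)
  data.frame(expected_rpv = as.numeric(expected),
             delta_rpv = delta,
             delta_rpv_percent = delta / model$mean_rpv_hc * 100,
             extrapolation_flag = attr(expected, "extrapolated"))
}

#' Score every subject of a cohort against a normative model
#'
#' @param model a [fit_normative()] model.
#' @param cohort a [as_cohort()] object.
#' @return A list with `scores` (data frame: subject_id, group,
#'   age_years, rpv_percent, expected_rpv, delta_rpv, delta_rpv_percent,
#'   extrapolation_flag) and `summary` (the [group_summary()] of patient
#'   `delta_rpv_percent` -- or of all subjects when no patients are
#'   present -- plus `n_negative`, the count of patients with negative
#'   deviation).
#' @export
score_cohort <- function(model, cohort) {
  if (is.null(cohort$rpv_percent)) cohort <- add_volumetry(cohort)
  sc <- score_patient(model, cohort$age_years, cohort$rpv_percent)
  scores <- cbind(
    data.frame(subject_id = cohort$subject_id, group = cohort$group,
               age_years = cohort$age_years,
               rpv_percent = cohort$rpv_percent, stringsAsFactors = FALSE),
    sc)
  ms <- scores$group == "MS"
  target <- if (any(ms)) scores$delta_rpv_percent[ms] else scores$delta_rpv_percent
  smry <- group_summary(target)
  smry$n_negative <- sum(scores$delta_rpv_percent[ms] < 0)
  list(scores = scores, summary = smry)
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> RPV_HC(Age) = %.4f %+.5f x Age\n",
              x$intercept, x$slope))
  cat(sprintf("  n = %d controls, ages %.1f-%.1f y; mean RPV = %.4f%%; residual SD = %.4f\n",
              x$n_hc, x$age_range_fit[1L], x$age_range_fit[2L],
              x$mean_rpv_hc, x$residual_sd))
  invisible(x)
}
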