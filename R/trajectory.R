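#' Trajectory models of deviation versus disease duration
#'
#' Two competing cross-sectional models of the age-corrected putamen
#' deviation (delta-RPV percent) as a function of disease duration D in
#' months:
#' \describe{
#'   \item{linear}{`deviation = slope * D + intercept` -- constant loss
#'     per month.}
#'   \item{log10}{`deviation = slope * log10(D) + intercept` --
#'     degressive loss, steep early and flattening later; defined only
#'     for D > 0.}
#' }
#' Both are fitted by closed-form ordinary least squares. Internally the
#' coefficients are always stored as `(slope, intercept)`; the
#' conventional report labelling `a` (slope) and `b` (intercept) is
#' available through [ab_coefficients()].
#'
#' @name trajectory
NULL

new_trajectory_fit <- function(model, durations, y) {
  n <- length(durations)
  x <- if (model == "log10") log10(durations) else durations
  fit <- stats::lm(y ~ x)
  res <- unname(stats::residuals(fit))
  structure(list(
    model = model,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = n,
    sse = sum(res^2),
    residuals = res,
    fitted = unname(stats::fitted(fit)),
    qq_correlation = qq_correlation(res),
    duration_range = range(durations)
  ), class = "trajectory_fit")
}

#' Fit the linear duration-trajectory model
#'
#' @param durations_months disease durations in months, n >= 3, not all
#'   equal.
#' @param delta_rpv_percent deviation scores, percent of mean control
#'   RPV.
#' @return A `trajectory_fit` object (see [trajectory]).
#' @export
fit_linear <- function(durations_months, delta_rpv_percent) {
  check_trajectory_input(durations_months, delta_rpv_percent)
  new_trajectory_fit("linear", durations_months, delta_rpv_percent)
}

#' Fit the logarithmic (log10-duration) trajectory model
#'
#' Least squares on the log10-transformed duration, equivalent to
#' `fit_linear(log10(durations), y)`.
#'
#' @inheritParams fit_linear
#' @return A `trajectory_fit` object (see [trajectory]).
#' @export
fit_log10 <- function(durations_months, delta_rpv_percent) {
  check_trajectory_input(durations_months, delta_rpv_percent)
  bad <- which(durations_months <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("log10 model undefined: non-positive duration at position %d",
                 bad[1L]), call. = FALSE)
  }
  new_trajectory_fit("log10", durations_months, delta_rpv_percent)
}

check_trajectory_input <- function(d, y) {
  if (length(d) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(d) < 3L) stop("n >= 3 required", call. = FALSE)
  if (stats::var(d) == 0) stop("degenerate fit: durations all equal", call. = FALSE)
  invisible(TRUE)
}

#' Predict deviation at given durations from a trajectory fit
#'
#' @param object a `trajectory_fit`.
#' @param durations_months durations in months (for the log10 model,
#'   strictly positive).
#' @param ... unused.
#' @return Predicted deviation, percent.
#' @export
predict.trajectory_fit <- function(object, durations_months, ...) {
  if (object$model == "log10") {
    if (any(durations_months <= 0)) {
      stop("log10 model undefined at non-positive durations", call. = FALSE)
    }
    object$slope * log10(durations_months) + object$intercept
  } else {
    object$slope * durations_months + object$intercept
  }
}

#' Conventional (a, b) labelling of trajectory coefficients
#'
#' Reports the fit as `a` = slope and `b` = intercept, the labelling
#' used for both the linear model (`deviation = a * D + b`) and the
#' logarithmic model (`deviation = a * log10(D) + b`).
#'
#' @param fit a `trajectory_fit`.
#' @return Named numeric vector `c(a = slope, b = intercept)`.
#' @export
ab_coefficients <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  c(a = fit$slope, b = fit$intercept)
}

#' Extrapolated atrophy-onset time from the linear model
#'
#' Solves the fitted linear trajectory for the duration at which the
#' predicted deviation is zero, `-intercept / slope`. A negative value
#' places the onset of putamen atrophy before the first clinical
#' symptoms. Defined for the linear model only: the logarithmic model
#' has no finite zero-duration value. The result is an extrapolation
#' whenever it falls outside the observed duration range and carries an
#' `"extrapolated"` attribute saying so.
#'
#' @param fit a linear `trajectory_fit` with nonzero slope.
#' @return Onset in months (may be negative).
#' @export
onset_months <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (fit$model != "linear") {
    stop("onset is defined for the linear model only", call. = FALSE)
  }
  if (fit$slope == 0) stop("undefined onset: slope is zero", call. = FALSE)
  onset <- -fit$intercept / fit$slope
  attr(onset, "extrapolated") <-
    onset < fit$duration_range[1L] || onset > fit$duration_range[2L]
  onset
}

#' Predicted additional volume loss over one decade
#'
#' `prediction(from) - prediction(from + 120 months)`. For the linear
#' model this is `|slope| * 120` regardless of the starting point; for a
#' declining log10 model it shrinks as `from_month` grows -- the
#' degressive-atrophy signature.
#'
#' @param fit a `trajectory_fit`.
#' @param from_month start of the decade, months (> 0 for the log10
#'   model).
#' @param horizon_months length of the window, default 120.
#' @return Loss in percent (positive when the deviation declines).
#' @export
decade_loss <- function(fit, from_month, horizon_months = 120) {
  predict(fit, from_month) - predict(fit, from_month + horizon_months)
}

qq_correlation <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || stats::sd(residuals) == 0) return(NA_real_)
  stats::cor(sort(residuals), stats::qnorm(stats::ppoints(n)))
}

#' Compare the linear and logarithmic trajectory fits
#'
#' Residual-based comparison of two fits of the same data: the sum of
#' squared errors is the primary criterion (lower wins) and the
#' normal-quantile correlation of each residual vector (correlation of
#' the sorted residuals with standard-normal plotting-position
#' quantiles, the numeric summary of a normal probability plot) is
#' reported as secondary evidence. Ties go to the linear model.
#'
#' @param linear_fit a linear `trajectory_fit`.
#' @param log_fit a log10 `trajectory_fit` on the same n observations.
#' @return An object of class `model_comparison`: list with
#'   `sse_linear`, `sse_log`, `qq_corr_linear`, `qq_corr_log`,
#'   `preferred`.
#' @export
compare_models <- function(linear_fit, log_fit) {
  stopifnot(inherits(linear_fit, "trajectory_fit"),
            inherits(log_fit, "trajectory_fit"))
  if (linear_fit$model != "linear" || log_fit$model != "log10") {
    stop("expected one linear and one log10 fit", call. = FALSE)
  }
  if (linear_fit$n != log_fit$n) {
    stop("fits are not on the same data: n differs", call. = FALSE)
  }
  structure(list(
    sse_linear = linear_fit$sse,
    sse_log = log_fit$sse,
    qq_corr_linear = linear_fit$qq_correlation,
    qq_corr_log = log_fit$qq_correlation,
    preferred = if (log_fit$sse < linear_fit$sse) "log10" else "linear"
  ), class = "model_comparison")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  form <- if (x$model == "log10") "%.3f x log10(D) %+.3f" else "%.4f x D %+.3f"
  cat(sprintf("<trajectory_fit:%s> deviation = %s (n = %d, SSE = %.1f, QQ-r = %.3f)\n",
              x$model, sprintf(form, x$slope, x$intercept), x$n, x$sse,
              x$qq_correlation))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> SSE linear = %.1f, log10 = %.1f; QQ-r %.3f vs %.3f; preferred: %s\n",
              x$sse_linear, x$sse_log, x$qq_corr_linear, x$qq_corr_log,
              x$preferred))
  invisible(x)
}
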