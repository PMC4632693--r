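#' Run the full putamen-atrophy analysis pipeline
#'
#' Orchestrates the analysis end to end: validate the cohort, compute
#' per-subject volumetry (APV, RPV), fit the age-normative model on the
#' controls, score every subject's age-corrected deviation, compare the
#' groups (pooled t-tests on APV, RPV, age, ICV and deviation; Yates
#' chi-squared on the sex table; ANCOVA of APV on age and sex), fit the
#' linear and logarithmic duration-trajectory models with onset
#' extrapolation and residual-based comparison, and correlate deviation
#' with lesion burden. Every number in the report is recomputable from
#' the cohort alone; the run is deterministic.
#'
#' When `out_dir` is given, the report is written as `report.json`, the
#' demographics and deviation tables as CSVs, and the two
#' deviation-versus-duration figures (linear and logarithmic fit) as
#' PNGs.
#'
#' @param cohort a [as_cohort()] object or a path to a cohort table
#'   readable by [read_cohort_table()].
#' @param out_dir optional output directory.
#' @param verbose print one progress line per stage?
#' @return An object of class `analysis_report` (a list; see Details).
#' @export
run_pipeline <- function(cohort, out_dir = NULL, verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  stopifnot(inherits(cohort, "cohort"))
  say <- function(...) if (verbose) message(sprintf(...))

  val <- validate_cohort(cohort)
  if (!val$pass) {
    stop("cohort failed validation:\n  ",
         paste(val$violations, collapse = "\n  "), call. = FALSE)
  }
  hc <- cohort[cohort$group == "HC", , drop = FALSE]
  ms <- cohort[cohort$group == "MS", , drop = FALSE]
  if (nrow(hc) < 3L) stop("need >= 3 controls to fit the normative model",
                          call. = FALSE)
  say("validated cohort: %d HC, %d MS", nrow(hc), nrow(ms))

  cohort <- add_volumetry(cohort)
  hc <- cohort[cohort$group == "HC", , drop = FALSE]
  ms <- cohort[cohort$group == "MS", , drop = FALSE]
  summary_table <- cohort_summary_table(cohort)

  model <- fit_normative(hc$age_years, hc$rpv_percent)
  say("normative model: intercept %.4f, slope %.5f", model$intercept, model$slope)
  ms_descriptive <- if (nrow(ms) >= 3L && stats::var(ms$age_years) > 0) {
    m <- fit_normative(ms$age_years, ms$rpv_percent)
    list(intercept = m$intercept, slope = m$slope, n = m$n_hc)
  }

  scored <- score_cohort(model, cohort)
  dev_ms <- scored$scores$delta_rpv_percent[scored$scores$group == "MS"]
  dev_hc <- scored$scores$delta_rpv_percent[scored$scores$group == "HC"]
  say("scored %d subjects; %d/%d patients below expectation",
      nrow(scored$scores), scored$summary$n_negative, nrow(ms))

  comparisons <- if (nrow(ms) >= 2L) {
    sex_tab <- rbind(c(sum(ms$sex == "F"), sum(ms$sex == "M")),
                     c(sum(hc$sex == "F"), sum(hc$sex == "M")))
    list(age = two_sample_t(ms$age_years, hc$age_years),
         icv = two_sample_t(ms$icv_mm3, hc$icv_mm3),
         apv = two_sample_t(ms$apv_mm3, hc$apv_mm3),
         rpv = two_sample_t(ms$rpv_percent, hc$rpv_percent),
         delta_rpv_percent = two_sample_t(dev_ms, dev_hc),
         sex = chi_squared_2x2(sex_tab, corrected = TRUE),
         percent_reduction_apv = percent_reduction(mean(ms$apv_mm3), mean(hc$apv_mm3)),
         percent_reduction_rpv = percent_reduction(mean(ms$rpv_percent), mean(hc$rpv_percent)),
         ancova_apv = if (nlevels(factor(cohort$sex)) == 2L)
           ancova(cohort$apv_mm3, cohort$age_years, cohort$sex))
  }

  dur_ok <- !is.na(ms$disease_duration_months) & ms$disease_duration_months > 0
  trajectory <- NULL
  if (sum(dur_ok) >= 3L && stats::var(ms$disease_duration_months[dur_ok]) > 0) {
    d <- ms$disease_duration_months[dur_ok]
    y <- dev_ms[dur_ok]
    lin <- fit_linear(d, y)
    lg <- fit_log10(d, y)
    onset <- onset_months(lin)
    trajectory <- list(
      linear = lin, log10 = lg,
      points = data.frame(subject_id = ms$subject_id[dur_ok],
                          duration = d, deviation = y,
                          stringsAsFactors = FALSE),
      onset_months = as.numeric(onset),
      onset_extrapolated = attr(onset, "extrapolated"),
      decade_loss_linear = decade_loss(lin, min(d)),
      comparison = compare_models(lin, lg))
    say("trajectory: linear a = %.4f, log10 a = %.3f, onset %.0f months, preferred %s",
        lin$slope, lg$slope, trajectory$onset_months,
        trajectory$comparison$preferred)
  } else {
    say("trajectory stage skipped: fewer than 3 usable disease durations")
  }

  associations <- if (nrow(ms) >= 3L) lesion_associations(scored$scores, cohort)

  report <- structure(list(
    n_hc = nrow(hc), n_ms = nrow(ms),
    summary_table = summary_table,
    normative = list(intercept = model$intercept, slope = model$slope,
                     n_hc = model$n_hc, residual_sd = model$residual_sd,
                     mean_rpv_hc = model$mean_rpv_hc,
                     age_range_fit = model$age_range_fit),
    ms_age_regression = ms_descriptive,
    deviation = scored,
    comparisons = comparisons,
    trajectory = trajectory,
    associations = associations,
    provenance = list(package_version = as.character(utils::packageVersion("putatrophy")),
                      source = attr(cohort, "provenance") %||% "unspecified")
  ), class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir, verbose = verbose)
  report
}

write_report <- function(report, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary_table,
                   file.path(out_dir, "summary_table.csv"), row.names = FALSE)
  utils::write.csv(report$deviation$scores,
                   file.path(out_dir, "deviation_table.csv"), row.names = FALSE)
  json <- report
  json$deviation$scores <- NULL  # kept in its own CSV
  json$trajectory$linear$residuals <- NULL
  json$trajectory$linear$fitted <- NULL
  json$trajectory$log10$residuals <- NULL
  json$trajectory$log10$fitted <- NULL
  if (!is.null(json$trajectory)) {
    json$trajectory$linear <- unclass(json$trajectory$linear)
    json$trajectory$log10 <- unclass(json$trajectory$log10)
    json$trajectory$comparison <- unclass(json$trajectory$comparison)
  }
  jsonlite::write_json(lapply(unclass(json), unclass),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  if (!is.null(report$trajectory)) {
    for (mod in c("linear", "log10")) {
      f <- file.path(out_dir, sprintf("deviation_vs_duration_%s.png", mod))
      tryCatch({
        p <- plot_trajectory(report, model = mod)
        ggplot2::ggsave(f, p, width = 6, height = 4.5, dpi = 150)
      }, error = function(e) warning("figure skipped: ", conditionMessage(e)))
    }
  }
  if (verbose) message("report written to ", out_dir)
  invisible(out_dir)
}

#' Scatter of deviation versus disease duration with a fitted trajectory
#'
#' Mirrors the study's trajectory figures: each patient's age-corrected
#' deviation against disease duration, overlaid with the fitted linear
#' or logarithmic curve.
#'
#' @param report an `analysis_report` whose trajectory stage ran.
#' @param model `"linear"` or `"log10"`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(report, model = c("log10", "linear")) {
  model <- match.arg(model)
  stopifnot(inherits(report, "analysis_report"))
  if (is.null(report$trajectory)) stop("report has no trajectory stage", call. = FALSE)
  fit <- report$trajectory[[model]]
  rng <- fit$duration_range
  grid <- data.frame(duration = seq(max(rng[1L], 1), rng[2L], length.out = 200))
  grid$pred <- predict(fit, grid$duration)
  duration <- deviation <- pred <- NULL  # satisfy aes() lookup in package scope
  ggplot2::ggplot() +
    ggplot2::geom_point(data = report$trajectory$points,
                        ggplot2::aes(x = duration, y = deviation), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = duration, y = pred),
                       linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Disease duration (months)",
                  y = expression(Delta * "RPV% (percent of mean HC RPV)"),
                  title = sprintf("%s trajectory: deviation = %.3f %s %+.3f",
                                  model, fit$slope,
                                  if (model == "log10") "x log10(D)" else "x D",
                                  fit$intercept)) +
    ggplot2::theme_minimal()
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d HC, %d MS\n", x$n_hc, x$n_ms))
  cat(sprintf("  normative: RPV_HC(Age) = %.4f %+.5f x Age (residual SD %.4f)\n",
              x$normative$intercept, x$normative$slope, x$normative$residual_sd))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  APV reduction %.1f%%, RPV reduction %.1f%%; deviation t = %.2f (df %d, p = %.3g)\n",
                x$comparisons$percent_reduction_apv,
                x$comparisons$percent_reduction_rpv,
                x$comparisons$delta_rpv_percent$statistic,
                x$comparisons$delta_rpv_percent$df,
                x$comparisons$delta_rpv_percent$p_value))
    cat(sprintf("  patients below age expectation: %d/%d\n",
                x$deviation$summary$n_negative, x$n_ms))
  }
  if (!is.null(x$trajectory)) {
    print(x$trajectory$linear); print(x$trajectory$log10)
    cat(sprintf("  onset (linear extrapolation): %.0f months; preferred model: %s\n",
                x$trajectory$onset_months, x$trajectory$comparison$preferred))
  }
  if (!is.null(x$associations)) {
    for (i in seq_len(nrow(x$associations))) {
      cat(sprintf("  deviation ~ %s: r = %.2f (n = %d, p = %.3g)\n",
                  x$associations$measure[i], x$associations$r[i],
                  x$associations$n[i], x$associations$p_value[i]))
    }
  }
  invisible(x)
}
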