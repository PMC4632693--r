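#' Absolute putamen volume
#'
#' APV is the sum of the left and right putamen volumes in mm^3.
#'
#' @param left,right hemispheric putamen volumes in mm^3, non-negative.
#' @return APV in mm^3 (vectorized).
#' @export
absolute_putamen_volume <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("putamen volumes must be non-negative", call. = FALSE)
  }
  left + right
}

#' Relative putamen volume
#'
#' RPV expresses the absolute putamen volume as a percentage of the
#' intracranial volume, `APV / ICV * 100`, removing the head-size
#' confound on raw volumes.
#'
#' @param apv absolute putamen volume, mm^3.
#' @param icv intracranial volume, mm^3, strictly positive.
#' @return RPV in percent of ICV (vectorized).
#' @export
relative_putamen_volume <- function(apv, icv) {
  if (any(icv <= 0, na.rm = TRUE)) stop("icv must be > 0", call. = FALSE)
  apv / icv * 100
}

#' Percent reduction of a patient-group mean relative to controls
#'
#' @param mean_ms patient-group mean.
#' @param mean_hc control-group mean, strictly positive.
#' @return `100 * (1 - mean_ms / mean_hc)`.
#' @export
percent_reduction <- function(mean_ms, mean_hc) {
  if (any(mean_hc <= 0)) stop("control mean must be > 0", call. = FALSE)
  100 * (1 - mean_ms / mean_hc)
}

#' Attach per-subject volumetry to a cohort
#'
#' Adds `apv_mm3` and `rpv_percent` columns.
#'
#' @param cohort a [as_cohort()] object.
#' @return The cohort with volumetry columns appended.
#' @export
add_volumetry <- function(cohort) {
  cohort$apv_mm3 <- absolute_putamen_volume(cohort$putamen_left_mm3,
                                            cohort$putamen_right_mm3)
  cohort$rpv_percent <- relative_putamen_volume(cohort$apv_mm3, cohort$icv_mm3)
  cohort
}

#' Pooled-variance two-sided two-sample t-test
#'
#' Student's t-test with the pooled variance estimate, so the degrees of
#' freedom are `n_a + n_b - 2`. When both samples are constant and their
#' means equal, the statistic is defined as 0 with p = 1.
#'
#' @param values_a,values_b numeric samples, each of size >= 2.
#' @return A list with `statistic`, `df`, `p_value`, and `kind`.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    df <- length(values_a) + length(values_b) - 2
    if (mean(values_a) == mean(values_b)) {
      return(list(statistic = 0, df = df, p_value = 1, kind = "t_two_sided"))
    }
    return(list(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                df = df, p_value = 0, kind = "t_two_sided"))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, kind = "t_two_sided")
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' With `corrected = TRUE` (the default) the Yates continuity correction
#' is applied (0.5 subtracted from each |observed - expected| before
#' squaring); df = 1 in both variants.
#'
#' @param counts a 2x2 matrix of non-negative counts with positive
#'   margins.
#' @param corrected apply the Yates continuity correction?
#' @return A list with `statistic`, `df`, `p_value`, and `kind`.
#' @export
chi_squared_2x2 <- function(counts, corrected = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = corrected))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value,
       kind = if (corrected) "chi2_yates" else "chi2_plain")
}

#' Two-predictor ANCOVA (age + sex, no interaction)
#'
#' Ordinary least squares of the dependent variable on an intercept,
#' continuous age, and categorical sex. Each predictor's F (1 numerator
#' df) and p come from its partial sum of squares, which for this
#' two-main-effect model is the type-III decomposition.
#'
#' @param dependent numeric response.
#' @param age numeric covariate.
#' @param sex factor or character with both levels present.
#' @return A data frame with one row per predictor: `term`, `F`, `df1`,
#'   `df2`, `p_value`.
#' @export
ancova <- function(dependent, age, sex) {
  sex <- factor(sex)
  if (nlevels(droplevels(sex)) < 2L) {
    stop("degenerate design: both sexes must be present", call. = FALSE)
  }
  if (length(dependent) < 4L) stop("n >= 4 required", call. = FALSE)
  fit <- stats::lm(dependent ~ age + sex)
  dr <- stats::drop1(fit, scope = ~ age + sex, test = "F")
  terms <- rownames(dr)[-1L]
  data.frame(term = sub("^sex$", "sex", terms),
             F = dr$`F value`[-1L],
             df1 = dr$Df[-1L],
             df2 = stats::df.residual(fit),
             p_value = dr$`Pr(>F)`[-1L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Seven-number descriptive summary of a sample
#'
#' Mean, median, min, max, lower and upper quartile, and standard
#' deviation, the descriptive layout used for cohort demographics
#' tables. Quartiles use linear interpolation between order statistics
#' (`quantile` type 7).
#'
#' @param values numeric, n >= 1.
#' @return A list with `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `lower_quartile`, `upper_quartile`.
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       median = q[2L], min = min(values), max = max(values),
       lower_quartile = q[1L], upper_quartile = q[3L])
}

#' Demographics table for a cohort
#'
#' One row per variable and group, with the seven descriptive statistics
#' of [group_summary()]. Intracranial volume is reported in litres.
#'
#' @param cohort a [as_cohort()] object (volumetry columns added if
#'   absent).
#' @return A data frame.
#' @export
cohort_summary_table <- function(cohort) {
  if (is.null(cohort$apv_mm3)) cohort <- add_volumetry(cohort)
  vars <- list(
    "Age/years" = function(d) d$age_years,
    "Intracranial volume/L" = function(d) d$icv_mm3 / 1e6,
    "Absolute putamen volume/mm3" = function(d) d$apv_mm3,
    "Relative putamen volume/%" = function(d) d$rpv_percent,
    "Disease duration/months" = function(d) d$disease_duration_months,
    "Expanded Disability Status Scale" = function(d) d$edss,
    "WM lesion volume (FLAIR)/mL" = function(d) d$lesion_flair_ml,
    "WM lesion volume (T1w)/mL" = function(d) d$lesion_t1_ml)
  rows <- list()
  for (grp in c("MS", "HC")) {
    d <- cohort[cohort$group == grp, , drop = FALSE]
    if (nrow(d) == 0L) next
    for (v in names(vars)) {
      x <- vars[[v]](d)
      x <- x[!is.na(x)]
      if (length(x) == 0L) next
      s <- group_summary(x)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, variable = v, n = s$n, mean = s$mean, median = s$median,
        min = s$min, max = s$max, lower_quartile = s$lower_quartile,
        upper_quartile = s$upper_quartile, sd = s$sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
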