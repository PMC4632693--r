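#' Configuration of the synthetic-cohort generator
#'
#' Bundles every generative parameter of the simulated study: group
#' sizes and demographics (truncated-normal ages, sex frequencies),
#' intracranial volume (group mean/SD plus a male head-size offset
#' routed so the group marginal mean is preserved), the healthy-control
#' age-normative relation generating control RPV, the logarithmic
#' decline generating patient deviations, the truncated log-normal
#' disease-duration distribution, lesion-volume marginals with a
#' Gaussian-copula link to atrophy, and the left/right volume split.
#' Defaults reproduce the cross-sectional RRMS study structure the
#' package analyzes: 26 controls and 68 patients, control ages 37.0
#' (SD 13.8) years, patient ages 36.5 (SD 9.8) years, ICV near 1.5 L,
#' control RPV declining from 0.916 percent of ICV by 0.0038 per year
#' (residual SD 0.05), patient deviation
#' `5.116 - 13.449 * log10(duration)` percent with additive noise SD 8,
#' durations with median 70.5 / mean 96.1 months truncated to [4, 313],
#' and lesion volumes with means 4.0 (T1w) / 9.6 (FLAIR) mL correlated
#' about 0.66/0.67 with atrophy severity.
#'
#' @param seed integer seed; identical seed and config give a
#'   bit-identical cohort. Patients use `seed + 1` internally so control
#'   and patient draws are independent yet reproducible separately.
#' @param n_hc,n_ms group sizes.
#' @param hc_age,ms_age lists `(mean, sd, min, max)` for truncated
#'   normal age draws, years.
#' @param sex_prob_female named list with per-group probability of a
#'   female participant.
#' @param icv list: per-group `mean` and `sd` (mm^3) and `male_offset`
#'   (mm^3), applied centered within group.
#' @param normative list `(intercept, slope, residual_sd)` of the
#'   control RPV-on-age relation, percent of ICV.
#' @param decline list `(slope, intercept, noise_sd)` of the patient
#'   log10-duration deviation model, percent.
#' @param duration list `(median, mean, min, max)` of the log-normal
#'   disease-duration distribution, months.
#' @param lesion list of per-contrast `(mean, median)` mL and the
#'   target Pearson correlation with `-deviation`.
#' @param edss list `(mean, sd, max)`; drawn on a half-point grid,
#'   descriptive only.
#' @param laterality_split expected left fraction of putamen volume;
#'   jittered by +/- `laterality_jitter` per subject.
#' @param laterality_jitter half-width of the uniform split jitter.
#' @return An object of class `synth_config` (a list).
#' @export
synth_config <- function(
    seed = 1L,
    n_hc = 26L,
    n_ms = 68L,
    hc_age = list(mean = 37.0, sd = 13.8, min = 20, max = 70),
    ms_age = list(mean = 36.5, sd = 9.8, min = 19, max = 56),
    sex_prob_female = list(hc = 19 / 26, ms = 45 / 68),
    icv = list(hc_mean = 1.51e6, hc_sd = 0.15e6,
               ms_mean = 1.50e6, ms_sd = 0.14e6,
               male_offset = 8e4),
    normative = list(intercept = 0.916, slope = -0.0038, residual_sd = 0.05),
    decline = list(slope = -13.449, intercept = 5.116, noise_sd = 8.0),
    duration = list(median = 70.5, mean = 96.1, min = 4, max = 313),
    lesion = list(t1 = list(mean = 4.0, median = 2.7, target_r = 0.66),
                  flair = list(mean = 9.6, median = 4.9, target_r = 0.67)),
    edss = list(mean = 2.1, sd = 1.3, max = 6),
    laterality_split = 0.5,
    laterality_jitter = 0.01) {
  stopifnot(hc_age$min < hc_age$max, ms_age$min < ms_age$max,
            duration$min < duration$max, duration$min > 0,
            n_hc >= 1L, n_ms >= 1L)
  structure(list(seed = as.integer(seed), n_hc = as.integer(n_hc),
                 n_ms = as.integer(n_ms), hc_age = hc_age, ms_age = ms_age,
                 sex_prob_female = sex_prob_female, icv = icv,
                 normative = normative, decline = decline,
                 duration = duration, lesion = lesion, edss = edss,
                 laterality_split = laterality_split,
                 laterality_jitter = laterality_jitter),
            class = "synth_config")
}

# Mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# Location of the underlying normal such that the truncated mean equals
# the configured target (asymmetric bounds otherwise bias the mean).
truncnorm_location <- function(target, sd, lo, hi) {
  stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
                 interval = c(lo, hi), extendInt = "yes", tol = 1e-8)$root
}

# Rejection sampler for a truncated normal; bounds are assumed to keep
# the acceptance probability away from zero (demographic-scale use).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

rtrunclnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# log-normal (meanlog, sdlog) matching a target median and mean:
# median = exp(mu), mean = exp(mu + sigma^2/2).
lnorm_from_median_mean <- function(median, mean) {
  stopifnot(mean >= median, median > 0)
  list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

# Centered sex offset: males get +p_female*offset, females
# -p_male*offset, so the group marginal mean equals `mean` exactly.
draw_icv <- function(sex, mean, sd, male_offset, p_female) {
  base <- stats::rnorm(length(sex), mean, sd)
  shift <- ifelse(sex == "M", p_female * male_offset,
                  -(1 - p_female) * male_offset)
  pmin(pmax(base + shift, 9.2e5), 2.18e6)
}

split_putamen <- function(apv, split, jitter) {
  f <- split + stats::runif(length(apv), -jitter, jitter)
  list(left = apv * f, right = apv * (1 - f))
}

#' Generate a synthetic healthy-control cohort
#'
#' Draws age, sex, and ICV, sets each control's RPV on the normative
#' line plus Gaussian residual noise, converts to an absolute putamen
#' volume, and splits it into hemispheres.
#'
#' @param config a [synth_config()].
#' @return A [as_cohort()] object of `config$n_hc` controls.
#' @export
generate_hc <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_hc
  a <- config$hc_age
  age <- rtruncnorm(n, truncnorm_location(a$mean, a$sd, a$min, a$max),
                    a$sd, a$min, a$max)
  sex <- ifelse(stats::runif(n) < config$sex_prob_female$hc, "F", "M")
  icv <- draw_icv(sex, config$icv$hc_mean, config$icv$hc_sd,
                  config$icv$male_offset, config$sex_prob_female$hc)
  nm <- config$normative
  rpv <- nm$intercept + nm$slope * age + stats::rnorm(n, 0, nm$residual_sd)
  apv <- rpv * icv / 100
  lr <- split_putamen(apv, config$laterality_split, config$laterality_jitter)
  as_cohort(data.frame(
    subject_id = sprintf("HC%03d", seq_len(n)), group = "HC",
    age_years = age, sex = sex, icv_mm3 = icv,
    putamen_left_mm3 = lr$left, putamen_right_mm3 = lr$right,
    stringsAsFactors = FALSE), provenance = "synthetic")
}

#' Generate a synthetic patient cohort
#'
#' Draws demographics and a truncated log-normal disease duration,
#' computes each patient's true age-corrected deviation from the
#' logarithmic decline model plus Gaussian noise, and inverts the
#' deviation-scoring definitions to recover the observed RPV:
#' `RPV = normative(age) + deviation * mean_control_RPV / 100`, where
#' the denominator is the true normative surface evaluated at the
#' control mean age. Lesion volumes are linked to atrophy severity by a
#' rank-based Gaussian copula whose latent correlation is chosen (via
#' the log-normal attenuation factor `sdlog / sqrt(exp(sdlog^2) - 1)`)
#' to hit the target Pearson correlation on the raw scale. EDSS is a
#' clamped half-point draw, descriptive only. Generation always goes
#' through the true normative surface, never a fitted one, so
#' downstream recovery measures estimation error.
#'
#' @param config a [synth_config()].
#' @return A [as_cohort()] object of `config$n_ms` patients with a
#'   `"truth"` attribute (data frame of each subject's true deviation).
#' @export
generate_ms <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_ms
  a <- config$ms_age
  age <- rtruncnorm(n, truncnorm_location(a$mean, a$sd, a$min, a$max),
                    a$sd, a$min, a$max)
  sex <- ifelse(stats::runif(n) < config$sex_prob_female$ms, "F", "M")
  icv <- draw_icv(sex, config$icv$ms_mean, config$icv$ms_sd,
                  config$icv$male_offset, config$sex_prob_female$ms)
  dur_par <- lnorm_from_median_mean(config$duration$median, config$duration$mean)
  duration <- rtrunclnorm(n, dur_par$meanlog, dur_par$sdlog,
                          config$duration$min, config$duration$max)
  dc <- config$decline
  delta_true <- dc$intercept + dc$slope * log10(duration) +
    stats::rnorm(n, 0, dc$noise_sd)
  nm <- config$normative
  mean_rpv_hc_true <- nm$intercept + nm$slope * config$hc_age$mean
  rpv <- nm$intercept + nm$slope * age + delta_true * mean_rpv_hc_true / 100
  apv <- pmax(rpv * icv / 100, 0)
  lr <- split_putamen(apv, config$laterality_split, config$laterality_jitter)

  z_dev <- stats::qnorm(rank(-delta_true, ties.method = "first") / (n + 1))
  lesion_draw <- function(par) {
    lp <- lnorm_from_median_mean(par$median, par$mean)
    atten <- lp$sdlog / sqrt(exp(lp$sdlog^2) - 1)
    rho <- min(par$target_r / atten, 0.99)
    z <- rho * z_dev + sqrt(1 - rho^2) * stats::rnorm(n)
    exp(lp$meanlog + lp$sdlog * z)
  }
  lesion_t1 <- lesion_draw(config$lesion$t1)
  lesion_flair <- lesion_draw(config$lesion$flair)
  edss <- pmin(pmax(round(stats::rnorm(n, config$edss$mean, config$edss$sd) * 2) / 2,
                    0), config$edss$max)

  cohort <- as_cohort(data.frame(
    subject_id = sprintf("MS%03d", seq_len(n)), group = "MS",
    age_years = age, sex = sex, icv_mm3 = icv,
    putamen_left_mm3 = lr$left, putamen_right_mm3 = lr$right,
    disease_duration_months = duration, edss = edss,
    lesion_t1_ml = lesion_t1, lesion_flair_ml = lesion_flair,
    stringsAsFactors = FALSE), provenance = "synthetic")
  attr(cohort, "truth") <- data.frame(
    subject_id = cohort$subject_id, delta_rpv_percent_true = delta_true,
    stringsAsFactors = FALSE)
  cohort
}

#' Generate a full synthetic study (controls + patients)
#'
#' Unions [generate_hc()] and [generate_ms()] and returns the cohort
#' together with a machine-readable ground-truth sidecar for
#' parameter-recovery tests. When `out_dir` is given, `cohort.csv` and
#' `truth.json` are written there.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return A list with `cohort` (a [as_cohort()]) and `truth` (list:
#'   generative coefficients and per-patient true deviations).
#' @export
generate_study <- function(config = synth_config(), out_dir = NULL) {
  hc <- generate_hc(config)
  ms <- generate_ms(config)
  truth_ms <- attr(ms, "truth")
  attr(ms, "truth") <- NULL
  cohort <- as_cohort(rbind(as.data.frame(hc), as.data.frame(ms)),
                      provenance = sprintf("synthetic (seed %d)", config$seed))
  truth <- list(
    seed = config$seed,
    normative = config$normative,
    decline = config$decline,
    mean_rpv_hc_true = config$normative$intercept +
      config$normative$slope * config$hc_age$mean,
    per_subject = truth_ms)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(cohort = cohort, truth = truth)
}

#' Write a synthetic aseg.stats fixture for one subject
#'
#' Emits a minimal but convention-conforming FreeSurfer `aseg.stats`
#' text (header measures, `TableCol`/`ColHeaders` lines, segmentation
#' rows) carrying the given volumes, for exercising the parser without
#' any imaging run.
#'
#' @param putamen_left_mm3,putamen_right_mm3,icv_mm3 volumes to embed.
#' @param path optional file to write.
#' @return The lines, invisibly if written to `path`.
#' @export
synthetic_aseg_stats <- function(putamen_left_mm3, putamen_right_mm3,
                                 icv_mm3, path = NULL) {
  lines <- c(
    "# Title Segmentation Statistics",
    "# generating_program synthetic",
    sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %.6f, mm^3", icv_mm3),
    "# NTableCols 5",
    "# TableCol  1 ColHeader Index",
    "# TableCol  2 ColHeader SegId",
    "# TableCol  3 ColHeader NVoxels",
    "# TableCol  4 ColHeader Volume_mm3",
    "# TableCol  5 ColHeader StructName",
    "# ColHeaders  Index SegId NVoxels Volume_mm3 StructName",
    sprintf("  1  12  %d  %.1f  Left-Putamen", round(putamen_left_mm3), putamen_left_mm3),
    sprintf("  2  51  %d  %.1f  Right-Putamen", round(putamen_right_mm3), putamen_right_mm3),
    "  3  10  7200  7200.0  Left-Thalamus")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
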