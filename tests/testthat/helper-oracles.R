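# Independent oracles and small fixture builders used across the suite.

# Brute-force least squares for y ~ 1 + x: gradient-based minimization
# of the SSE surface in a centered parameterization, independent of
# lm()'s linear algebra.
brute_force_ls <- function(x, y) {
  xc <- x - mean(x)
  sse <- function(par) sum((y - par[1] - par[2] * xc)^2)
  grad <- function(par) {
    r <- y - par[1] - par[2] * xc
    c(-2 * sum(r), -2 * sum(r * xc))
  }
  opt <- stats::optim(c(mean(y), 0), sse, gr = grad, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 10000))
  c(intercept = opt$par[1] - opt$par[2] * mean(x), slope = opt$par[2])
}

# Pooled two-sample t computed from first principles.
hand_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# The published healthy-control and patient age regressions, rebuilt as
# normative models from noise-free points on the printed lines.
published_hc_model <- function() {
  ages <- 23:69
  fit_normative(ages, 0.916 - 0.0038 * ages)
}
published_ms_model <- function() {
  ages <- 19:56
  fit_normative(ages, 0.783 - 0.0043 * ages)
}

# The published linear and logarithmic duration fits, rebuilt from
# noise-free points on the printed curves.
published_linear_fit <- function() {
  d <- seq(4, 272, by = 4)
  fit_linear(d, -0.083 * d - 11.434)
}
published_log_fit <- function() {
  d <- seq(4, 272, by = 4)
  fit_log10(d, 5.116 - 13.449 * log10(d))
}

# Durations spread uniformly in log10 over the observed range.
log_uniform_durations <- function(n, lo = 4, hi = 313) {
  10^runif(n, log10(lo), log10(hi))
}

tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("h1", "h2", "h3", "m1", "m2", "m3"),
    group = c("HC", "HC", "HC", "MS", "MS", "MS"),
    age_years = c(25, 40, 60, 30, 45, 50),
    sex = c("F", "M", "F", "F", "M", "F"),
    icv_mm3 = c(1.5e6, 1.6e6, 1.45e6, 1.52e6, 1.48e6, 1.55e6),
    putamen_left_mm3 = c(6000, 5900, 5600, 4700, 4600, 4500),
    putamen_right_mm3 = c(6050, 5950, 5650, 4718, 4650, 4550),
    disease_duration_months = c(NA, NA, NA, 24, 60, 120),
    edss = c(NA, NA, NA, 1.5, 2.0, 3.5),
    lesion_t1_ml = c(NA, NA, NA, 2.5, 4.0, 6.0),
    lesion_flair_ml = c(NA, NA, NA, 5.0, 9.0, 14.0),
    stringsAsFactors = FALSE)
}
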