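test_that("noise-free data recover the published duration fits exactly", {
  lin <- published_linear_fit()
  expect_equal(lin$slope, -0.083, tolerance = 1e-10)
  expect_equal(lin$intercept, -11.434, tolerance = 1e-10)
  expect_equal(lin$sse, 0, tolerance = 1e-10)
  lg <- published_log_fit()
  expect_equal(lg$slope, -13.449, tolerance = 1e-10)
  expect_equal(lg$intercept, 5.116, tolerance = 1e-10)
  expect_equal(ab_coefficients(lg), c(a = -13.449, b = 5.116),
               tolerance = 1e-10)
})

test_that("fits are self-consistent and handle degenerate inputs", {
  d <- c(5, 30, 90, 200)
  y <- c(-8, -15, -20, -30)
  for (fit in list(fit_linear(d, y), fit_log10(d, y))) {
    expect_equal(fit$sse, sum(fit$residuals^2), tolerance = 1e-10)
    expect_equal(fit$residuals, y - predict(fit, d), tolerance = 1e-10)
    expect_equal(fit$n, 4)
  }
  const <- fit_linear(d, rep(-15, 4))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$intercept, -15)
  expect_error(fit_linear(c(10, 10, 10), y[1:3]), "degenerate")
  expect_error(fit_log10(c(0, 10, 20), y[1:3]), "non-positive")
  expect_error(fit_linear(d[1:2], y[1:2]), "n >= 3")
})

test_that("the published log model evaluates to the expected deviations", {
  lg <- published_log_fit()
  expect_equal(predict(lg, 50), -17.73, tolerance = 1e-2)
  expect_equal(predict(lg, 1), 5.116, tolerance = 1e-9)  # log10(1) = 0
  expect_equal(predict(lg, 100), 5.116 - 13.449 * 2, tolerance = 1e-9)
  expect_error(predict(lg, 0), "non-positive")
})

test_that("log10 fitting equals linear fitting of the transformed axis", {
  set.seed(17)
  for (i in 1:6) {
    d <- 10^runif(12, log10(4), log10(313))
    y <- rnorm(12, -20, 8)
    lg <- fit_log10(d, y)
    lin <- fit_linear(log10(d), y)
    expect_equal(lg$slope, lin$slope, tolerance = 1e-12)
    expect_equal(lg$intercept, lin$intercept, tolerance = 1e-12)
    expect_equal(lg$sse, lin$sse, tolerance = 1e-10)
  }
})

test_that("both fitters agree with a brute-force least-squares oracle", {
  set.seed(23)
  for (i in 1:6) {
    n <- sample(3:10, 1)
    d <- sort(runif(n, 4, 313))
    y <- rnorm(n, -15, 10)
    lin <- fit_linear(d, y)
    bf <- brute_force_ls(d, y)
    expect_equal(lin$slope, unname(bf["slope"]), tolerance = 1e-6)
    expect_equal(lin$intercept, unname(bf["intercept"]), tolerance = 1e-6)
    lg <- fit_log10(d, y)
    bfl <- brute_force_ls(log10(d), y)
    expect_equal(lg$slope, unname(bfl["slope"]), tolerance = 1e-6)
    expect_equal(lg$intercept, unname(bfl["intercept"]), tolerance = 1e-6)
  }
})

test_that("onset extrapolation solves the linear model's root", {
  lin <- published_linear_fit()
  onset <- onset_months(lin)
  expect_equal(as.numeric(onset), -137.759, tolerance = 1e-2)
  expect_equal(round(as.numeric(onset)), -138)
  expect_true(attr(onset, "extrapolated"))
  mk <- function(slope, intercept) {
    d <- c(10, 50, 100)
    fit_linear(d, slope * d + intercept)
  }
  expect_equal(as.numeric(onset_months(mk(-1, 0))), 0, tolerance = 1e-10)
  expect_equal(as.numeric(onset_months(mk(-0.5, -5))), -10, tolerance = 1e-10)
  expect_error(onset_months(published_log_fit()), "linear model only")
  flat <- published_linear_fit(); flat$slope <- 0
  expect_error(onset_months(flat), "slope is zero")
})

test_that("decade loss is constant for linear and degressive for log fits", {
  lin <- published_linear_fit()
  for (from in c(0, 12, 120, 240)) {
    expect_equal(decade_loss(lin, from), 9.96, tolerance = 1e-9)
  }
  expect_equal(round(decade_loss(lin, 7)), 10)
  lg <- published_log_fit()
  expect_equal(decade_loss(lg, 120), 13.449 * log10(2), tolerance = 1e-9)
  starts <- c(4, 12, 40, 120, 240, 500)
  losses <- sapply(starts, function(s) decade_loss(lg, s))
  expect_true(all(diff(losses) < 0))  # strictly decreasing in from_month
  expect_true(all(losses > 0))        # a declining fit keeps losing volume
  expect_equal(decade_loss(lg, 60, horizon_months = 0), 0)
})

test_that("residual comparison prefers the generating model", {
  set.seed(31)
  nsim <- 300
  pick <- function(gen_log) {
    d <- log_uniform_durations(68)
    y <- if (gen_log) 5.116 - 13.449 * log10(d) + rnorm(68, 0, 8)
         else -0.083 * d - 11.434 + rnorm(68, 0, 8)
    compare_models(fit_linear(d, y), fit_log10(d, y))$preferred
  }
  log_rate <- mean(replicate(nsim, pick(TRUE)) == "log10")
  lin_rate <- mean(replicate(nsim, pick(FALSE)) == "linear")
  # true rates at this design and noise are ~0.95 (log) and ~0.94
  # (linear); bounds sit >3 MC-SE below them
  expect_gte(log_rate, 0.90)
  expect_gte(lin_rate, 0.90)
})

test_that("comparison reports both diagnostics and breaks ties to linear", {
  d <- c(6, 20, 60, 150, 280)
  y <- c(-5, -14, -19, -26, -33)
  cmp <- compare_models(fit_linear(d, y), fit_log10(d, y))
  expect_true(cmp$preferred %in% c("linear", "log10"))
  expect_true(cmp$qq_corr_linear >= 0 && cmp$qq_corr_linear <= 1)
  expect_true(cmp$qq_corr_log >= 0 && cmp$qq_corr_log <= 1)
  # exact tie (identical SSE) resolves to the linear reading
  tie_lin <- fit_linear(d, y); tie_log <- fit_log10(d, y)
  tie_log$sse <- tie_lin$sse
  expect_equal(compare_models(tie_lin, tie_log)$preferred, "linear")
  short <- fit_log10(d[1:4], y[1:4])
  expect_error(compare_models(tie_lin, short), "n differs")
})
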