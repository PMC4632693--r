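test_that("APV is the exact hemispheric sum and rejects negatives", {
  expect_equal(absolute_putamen_volume(4700, 4718), 9418)
  expect_equal(absolute_putamen_volume(0, 0), 0)
  expect_equal(absolute_putamen_volume(4718, 4700),
               absolute_putamen_volume(4700, 4718))
  expect_error(absolute_putamen_volume(-1, 100), "non-negative")
})

test_that("RPV normalizes by head size and is scale-invariant", {
  expect_equal(relative_putamen_volume(11733, 1.51e6), 0.777, tolerance = 1e-3)
  expect_equal(relative_putamen_volume(0, 1.5e6), 0)
  x <- c(3000, 9000, 12000)
  expect_equal(relative_putamen_volume(x, x * 100), rep(1, 3))
  for (k in c(0.5, 2, 17.3)) {
    expect_equal(relative_putamen_volume(9418 * k, 1.5e6 * k),
                 relative_putamen_volume(9418, 1.5e6))
  }
  expect_error(relative_putamen_volume(9000, 0), "icv")
})

test_that("percent reduction reproduces the published group contrasts", {
  expect_equal(round(percent_reduction(9418, 11733)), 20)
  expect_equal(round(percent_reduction(0.63, 0.78)), 19)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(1, 0), "> 0")
})

test_that("pooled t-test matches the hand formula and the printed df", {
  a <- c(1.2, 3.4, 2.2); b <- c(4.1, 5.0, 3.3)
  res <- two_sample_t(a, b)
  expect_equal(res$statistic, hand_pooled_t(a, b), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(two_sample_t(rnorm(68), rnorm(26))$df, 92)
  same <- c(1, 2, 3)
  expect_equal(two_sample_t(same, same)$statistic, 0)
  expect_equal(two_sample_t(same, same)$p_value, 1)
  expect_equal(two_sample_t(c(2, 2), c(2, 2)),
               list(statistic = 0, df = 2, p_value = 1, kind = "t_two_sided"))
})

test_that("t-test p agrees with a quadrature oracle on the t density", {
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(9, 0.5)
    res <- two_sample_t(a, b)
    dens <- function(t) {
      v <- res$df
      gamma((v + 1) / 2) / (sqrt(v * pi) * gamma(v / 2)) *
        (1 + t^2 / v)^(-(v + 1) / 2)
    }
    upper <- stats::integrate(dens, abs(res$statistic), Inf,
                              rel.tol = 1e-10)$value
    expect_equal(res$p_value, 2 * upper, tolerance = 1e-6)
  }
})

test_that("chi-squared on the study sex table reproduces both variants", {
  tab <- rbind(c(45, 23), c(19, 7))
  yates <- chi_squared_2x2(tab, corrected = TRUE)
  plain <- chi_squared_2x2(tab, corrected = FALSE)
  expect_equal(round(yates$p_value, 2), 0.69)
  expect_equal(round(plain$p_value, 2), 0.52)
  expect_equal(round(plain$statistic, 3), 0.412)
  expect_equal(yates$df, 1)
  # quadrature oracle for the df=1 chi-squared tail
  dens <- function(x) exp(-x / 2) / (sqrt(2 * pi) * sqrt(x))
  expect_equal(plain$p_value,
               stats::integrate(dens, plain$statistic, Inf, rel.tol = 1e-10)$value,
               tolerance = 1e-6)
})

test_that("a proportional 2x2 table gives statistic 0 and zero margins error", {
  res <- chi_squared_2x2(rbind(c(20, 10), c(40, 20)), corrected = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_squared_2x2(rbind(c(0, 0), c(4, 5))), "margins")
})

test_that("ancova recovers constructed age and sex effects", {
  set.seed(21)
  age <- runif(60, 20, 70)
  sex <- rep(c("F", "M"), 30)
  # pure age signal, no sex effect: age dominates, sex stays null
  res <- ancova(10000 - 30 * age + rnorm(60), age, sex)
  expect_lt(res$p_value[res$term == "age"], 1e-10)
  expect_gt(res$p_value[res$term == "sex"], 0.05)
  # additive sex offset 500 with unit noise: recovered within 3 SE
  y <- 9000 - 20 * age + 500 * (sex == "M") + rnorm(60)
  fit <- lm(y ~ age + sex)
  expect_lt(abs(coef(fit)[["sexM"]] - 500), 3 * summary(fit)$coefficients["sexM", 2])
  res2 <- ancova(y, age, sex)
  expect_gt(res2$F[res2$term == "sex"], 100)
  expect_error(ancova(y, age, rep("F", 60)), "both sexes")
})

test_that("ancova type-I error is calibrated under the null", {
  set.seed(99)
  nsim <- 400
  rejects <- replicate(nsim, {
    age <- runif(40, 20, 70)
    sex <- sample(rep(c("F", "M"), 20))
    res <- ancova(rnorm(40), age, sex)
    res$p_value <= 0.05
  })
  for (i in 1:2) {
    phat <- mean(rejects[i, ])
    ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / nsim)
    expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
  }
})

test_that("group_summary returns the seven ordered statistics", {
  s <- group_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$lower_quartile, 2)
  expect_equal(s$upper_quartile, 4); expect_equal(s$n, 5)
  expect_equal(group_summary(rep(7, 4))$sd, 0)
  with(group_summary(rexp(50)), {
    expect_true(min <= lower_quartile && lower_quartile <= median &&
                median <= upper_quartile && upper_quartile <= max)
  })
  expect_error(group_summary(numeric(0)), "empty")
})

test_that("synthetic control head sizes match the generative mean", {
  means <- sapply(1:200, function(s) mean(generate_hc(synth_config(seed = s))$icv_mm3))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1.51e6), 3 * mc_se + 1e3)
})
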