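exact_fit_data <- function(a = 2, b = 0.01, n = 10) {
  sali <- seq(100, 1000, length.out = n)
  tibble::tibble(year = 2008 + seq_len(n), sali = sali,
                 deaths = (a + b * sali)^2)
}

test_that("noiseless data generated from the model is fit exactly", {
  d <- exact_fit_data(a = 2, b = 0.01)
  fit <- fit_sali_regression(d)
  expect_equal(fit$slope, 0.01, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$df, 8L)
  # back-transform reproduces the generating death counts
  expect_equal(predict_deaths(fit, d$sali), d$deaths, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with typed errors", {
  d <- exact_fit_data()
  expect_error(fit_sali_regression(d[1:2, ]), "3", class = "sdli_data_error")
  flat <- d; flat$sali <- 5
  expect_error(fit_sali_regression(flat), class = "sdli_degenerate_error")
  neg <- d; neg$deaths[1] <- -1
  expect_error(fit_sali_regression(neg), class = "sdli_data_error")
  expect_error(fit_sali_regression(d[, c("year", "sali")]),
               class = "sdli_format_error")
  expect_error(fit_sali_regression(d, ci_level = 1.2),
               class = "sdli_config_error")
  # deaths = 0 years are allowed (sqrt(0) = 0)
  z <- d; z$deaths[1] <- 0
  expect_s3_class(fit_sali_regression(z), "sali_fit")
})

test_that("Durbin-Watson matches direct evaluation and its bounds", {
  expect_equal(durbin_watson(c(3, 3, 3, 3)), 0)
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3) # 12 / 4
  expect_error(durbin_watson(c(0, 0, 0)), class = "sdli_degenerate_error")
  expect_error(durbin_watson(1), class = "sdli_data_error")
  set.seed(42)
  for (i in 1:25) {
    e <- rnorm(sample(5:30, 1))
    dw <- durbin_watson(e)
    expect_true(dw >= 0 && dw <= 4)
    n <- length(e)
    oracle <- sum((e[-1] - e[-n])^2) / sum(e^2)
    expect_equal(dw, oracle, tolerance = 1e-12)
  }
})

test_that("Durbin-Watson agrees with the lmtest implementation on fitted models", {
  set.seed(7)
  d <- exact_fit_data()
  d$deaths <- (2 + 0.01 * d$sali + rnorm(10, 0, 0.4))^2
  fit <- fit_sali_regression(d)
  ref <- unname(lmtest::dwtest(fit$lm)$statistic)
  expect_equal(fit$durbin_watson, ref, tolerance = 1e-10)
})

test_that("predictions clamp a negative linear predictor at zero", {
  d <- exact_fit_data(a = 2, b = 0.01)
  fit <- fit_sali_regression(d)
  expect_warning(p <- predict_deaths(fit, -10000), "clamp")
  expect_equal(p, 0)
  # slope 0: prediction is the squared intercept everywhere
  flat <- tibble::tibble(year = 2001:2010, sali = 1:10, deaths = 9)
  ffit <- fit_sali_regression(flat)
  expect_equal(predict_deaths(ffit, c(0, 50)), c(9, 9), tolerance = 1e-9)
})

test_that("OLS invariants hold on randomly generated fits", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    d <- tibble::tibble(
      year = 2000 + seq_len(n),
      sali = runif(n, 100, 5000),
      deaths = round((10 + 0.01 * runif(n, 100, 5000) + rnorm(n))^2)
    )
    fit <- fit_sali_regression(d)
    e <- fit$data$residual
    expect_equal(sum(e), 0, tolerance = 1e-9)
    expect_equal(sum(e * fit$data$sali), 0, tolerance = 1e-6)
    # r^2 equals the squared Pearson correlation for simple regression
    expect_equal(fit$r_squared,
                 cor(fit$data$sali, fit$data$sqrt_deaths)^2, tolerance = 1e-9)
    # t^2 equals the one-predictor F statistic
    expect_equal(fit$t_stat^2,
                 unname(summary(fit$lm)$fstatistic["value"]), tolerance = 1e-9)
    expect_true(fit$slope_ci[["lower"]] <= fit$slope &&
                  fit$slope <= fit$slope_ci[["upper"]])
    expect_equal(fit$df, n - 2L)
  }
})

test_that("slope estimates are unbiased and the CI calibrated under Gaussian noise", {
  set.seed(2024)
  n <- 12
  sali <- seq(500, 6000, length.out = n)
  b <- 0.009; a <- 10; sigma <- 0.5
  reps <- 500
  slopes <- numeric(reps)
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    y <- pmax(0, a + b * sali + rnorm(n, 0, sigma))^2
    fit <- fit_sali_regression(tibble::tibble(year = seq_len(n), sali = sali,
                                              deaths = y))
    slopes[i] <- fit$slope
    covered[i] <- fit$slope_ci[["lower"]] <= b && b <= fit$slope_ci[["upper"]]
  }
  mc_se <- sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - b), 3 * mc_se)
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("residual diagnostics report skewness and emit the three plots", {
  # symmetric residuals orthogonal to the design: skewness is exactly 0
  x <- seq(100, 1000, length.out = 10)
  e <- c(-2, -1, 0, 1, 2, 2, 1, 0, -1, -2) # sum(e) = 0, sum(e * (1:10)) = 0
  sym <- tibble::tibble(year = 2009:2018, sali = x,
                        deaths = (5 + 0.01 * x + e)^2)
  sfit <- fit_sali_regression(sym)
  expect_equal(sfit$data$residual, e, tolerance = 1e-8)
  expect_equal(residual_diagnostics(sfit)$skewness, 0, tolerance = 1e-8)

  # exact fit: residuals vanish, plots are still produced
  d <- exact_fit_data()
  fit <- fit_sali_regression(d)
  diag <- residual_diagnostics(fit)
  expect_true(all(abs(fit$data$residual) < 1e-9))
  expect_named(diag$plots, c("histogram", "qq", "residual_vs_fitted"))

  dir <- withr::local_tempdir()
  diag2 <- residual_diagnostics(fit, dir = dir)
  expect_true(all(file.exists(diag2$paths)))

  # third-standardized-moment formula against an independent implementation
  set.seed(5)
  noisy <- d
  noisy$deaths <- (2 + 0.01 * noisy$sali + rexp(10) - 1)^2 # right-skewed noise
  nfit <- fit_sali_regression(noisy)
  ndiag <- residual_diagnostics(nfit)
  e <- nfit$data$residual
  expect_equal(ndiag$skewness, unname(e1071::skewness(e, type = 1)),
               tolerance = 1e-9)
})

test_that("tidy, glance and augment expose the published-style summaries", {
  d <- exact_fit_data()
  d$deaths <- (2 + 0.01 * d$sali + c(0.1, -0.2, 0.15, 0, -0.1, 0.2, -0.15, 0.05, -0.05, 0))^2
  fit <- fit_sali_regression(d)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "sali"))
  expect_equal(td$estimate[2], fit$slope)
  ref <- broom::tidy(fit$lm, conf.int = TRUE)
  expect_equal(td$estimate, ref$estimate)
  expect_equal(td$ci_low, ref$conf.low, ignore_attr = TRUE)
  expect_equal(td$ci_high, ref$conf.high, ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$r_squared, summary(fit$lm)$r.squared)
  expect_true(gl$durbin_watson >= 0 && gl$durbin_watson <= 4)
  aug <- augment(fit)
  expect_equal(aug$predicted_deaths, predict_deaths(fit, d$sali))
  expect_equal(aug$sqrt_observed - aug$fitted_sqrt, aug$residual)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
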