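#' Fit the square-root-scale regression of deaths on SALI
#'
#' Fits ordinary least squares of the square root of annual unintentional
#' overdose deaths on the Summed Annual Lethality Index:
#' \deqn{\sqrt{deaths_y} = a + b \cdot SALI_y + \varepsilon_y.}
#' The square-root transform stabilizes the right skew typical of annual
#' death counts. Inference on the slope is a two-sided t test with
#' `n - 2` degrees of freedom; residuals are stored in ascending year
#' order, as required by the Durbin-Watson statistic.
#'
#' @param data Data frame with columns `year`, `sali` and `deaths`
#'   (non-negative annual death counts), one row per year. A
#'   [compute_sali_series()] result joined to [annual_deaths()] output has
#'   this shape.
#' @param ci_level Two-sided confidence level for the slope interval
#'   (default 0.95).
#' @return An object of class `"sali_fit"`: a list with elements `slope`,
#'   `intercept`, `slope_ci`, `t_stat`, `df`, `p_value`, `r_squared`,
#'   `residuals` (year-ordered), `durbin_watson`, the underlying `lm` fit,
#'   and the year-ordered model `data` (with `sqrt_deaths`, `fitted_sqrt`,
#'   `residual` columns). Supports [tidy()], [glance()], [augment()],
#'   [predict_deaths()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(
#'   year = 2009:2018,
#'   sali = seq(100, 1000, length.out = 10),
#'   deaths = round((2 + 0.01 * seq(100, 1000, length.out = 10))^2)
#' )
#' fit <- fit_sali_regression(d)
#' glance(fit)
fit_sali_regression <- function(data, ci_level = 0.95) {
  required <- c("year", "sali", "deaths")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_format(paste0("`data` must have columns year, sali, deaths; missing: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(ci_level) || length(ci_level) != 1 ||
      ci_level <= 0 || ci_level >= 1) {
    abort_config("`ci_level` must be a single number in (0, 1).")
  }
  d <- as_tibble(data)[required]
  d <- d[complete.cases(d), ]
  if (any(d$deaths < 0)) abort_data("Negative death counts.")
  if (anyDuplicated(d$year)) abort_data("Duplicate years in regression data.")
  if (nrow(d) < 3) {
    abort_data(paste0("At least 3 matched (year, sali, deaths) points required; got ",
                      nrow(d), "."))
  }
  if (sd(d$sali) == 0) {
    abort_degenerate("SALI has zero variance across years; slope is unidentifiable.")
  }
  d <- arrange(d, .data$year)
  d$sqrt_deaths <- sqrt(d$deaths)

  fit <- lm(sqrt_deaths ~ sali, data = d)
  s <- summary(fit)
  ci <- confint(fit, "sali", level = ci_level)
  d$fitted_sqrt <- as.numeric(fitted(fit))
  d$residual <- as.numeric(residuals(fit))

  structure(
    list(
      slope = unname(coef(fit)["sali"]),
      intercept = unname(coef(fit)["(Intercept)"]),
      slope_ci = c(lower = ci[1, 1], upper = ci[1, 2]),
      ci_level = ci_level,
      t_stat = unname(s$coefficients["sali", "t value"]),
      df = fit$df.residual,
      p_value = unname(s$coefficients["sali", "Pr(>|t|)"]),
      r_squared = s$r.squared,
      residuals = setNames(d$residual, d$year),
      durbin_watson = durbin_watson(d$residual),
      data = d,
      lm = fit
    ),
    class = "sali_fit"
  )
}

#' Durbin-Watson statistic
#'
#' Computes \eqn{\sum_{t=2}^{n} (e_t - e_{t-1})^2 / \sum_{t=1}^{n} e_t^2}
#' on a time-ordered residual vector. Values near 2 indicate no first-order
#' autocorrelation; the statistic is bounded in \[0, 4\] and equals 0 only
#' when all successive differences vanish.
#'
#' @param residuals Numeric vector of residuals in time order, length at
#'   least 2 and not all zero.
#' @return The statistic, a real number in \[0, 4\].
#' @export
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) abort_data("Durbin-Watson needs at least 2 residuals.")
  denom <- sum(residuals^2)
  if (denom == 0) abort_degenerate("Durbin-Watson undefined: all residuals are zero.")
  sum(diff(residuals)^2) / denom
}

#' Predict annual deaths from a SALI value
#'
#' Back-transforms the linear predictor fitted on the square-root scale:
#' the predicted death count is `max(0, intercept + slope * sali)^2`. The
#' linear predictor is clamped at zero before squaring (with a warning)
#' under extreme extrapolation; no retransformation bias correction is
#' applied, so predictions correspond directly to the fitted line.
#'
#' @param result A `"sali_fit"` from [fit_sali_regression()].
#' @param sali_value Numeric vector of SALI values.
#' @return Numeric vector of predicted (non-negative) death counts.
#' @export
predict_deaths <- function(result, sali_value) {
  stopifnot(inherits(result, "sali_fit"))
  eta <- result$intercept + result$slope * sali_value
  if (any(eta < 0)) {
    warn("Negative linear predictor clamped to 0 before back-transform.")
    eta <- pmax(eta, 0)
  }
  eta^2
}

#' @export
predict.sali_fit <- function(object, newdata = NULL, ...) {
  sali <- if (is.null(newdata)) object$data$sali else newdata$sali
  predict_deaths(object, sali)
}

# Third standardized moment (population form): m3 / m2^(3/2).
moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 == 0) return(0)
  (sum((x - m)^3) / n) / m2^1.5
}

#' Residual diagnostics for a SALI regression
#'
#' Descriptive diagnostics mirroring the visual checks of the method:
#' residual skewness (third standardized moment), standardized residuals,
#' and three plots — histogram, normal Q-Q, and residuals vs fitted. No
#' automated pass/fail is applied; the plots are for visual inspection of
#' normality and homoscedasticity.
#'
#' @param result A `"sali_fit"` from [fit_sali_regression()].
#' @param dir Optional directory; when given, the three plots are written
#'   as PNG files there and their paths returned.
#' @return A list with `skewness`, `std_residuals` (tibble `year`,
#'   `residual`, `std_residual`), `plots` (named list of ggplot objects)
#'   and `paths` (named file paths, or `NULL` when `dir` is missing).
#' @export
residual_diagnostics <- function(result, dir = NULL) {
  stopifnot(inherits(result, "sali_fit"))
  e <- result$data$residual
  s <- sd(e)
  std <- if (isTRUE(s > 0)) e / s else e * 0
  tab <- tibble(year = result$data$year, residual = e, std_residual = std)

  df <- result$data
  plots <- list(
    histogram = ggplot2::ggplot(df, ggplot2::aes(x = .data$residual)) +
      ggplot2::geom_histogram(bins = max(5L, ceiling(nrow(df) / 2)),
                              fill = "grey35", colour = "white") +
      ggplot2::labs(x = "Residual (sqrt-death scale)", y = "Count",
                    title = "Residual histogram"),
    qq = ggplot2::ggplot(tab, ggplot2::aes(sample = .data$std_residual)) +
      ggplot2::stat_qq() + ggplot2::stat_qq_line() +
      ggplot2::labs(x = "Theoretical quantiles", y = "Standardized residuals",
                    title = "Normal Q-Q"),
    residual_vs_fitted = ggplot2::ggplot(
      df, ggplot2::aes(x = .data$fitted_sqrt, y = .data$residual)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Fitted (sqrt-death scale)", y = "Residual",
                    title = "Residuals vs fitted")
  )

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(plots), function(nm) {
      p <- file.path(dir, paste0("residual_", nm, ".png"))
      ggplot2::ggsave(p, plots[[nm]], width = 5, height = 4, dpi = 120)
      p
    }, character(1))
  }

  list(skewness = moment_skewness(e), std_residuals = tab,
       plots = plots, paths = paths)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a SALI regression fit
#'
#' @param x A `"sali_fit"` object.
#' @param ... Unused.
#' @return One row per model term with estimate, confidence bounds,
#'   t statistic, degrees of freedom and p value.
#' @method tidy sali_fit
#' @export
tidy.sali_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  ci <- confint(x$lm, level = x$ci_level)
  tibble(
    term = c("intercept", "sali"),
    estimate = c(x$intercept, x$slope),
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    t = s[, "t value"],
    df = x$df,
    p = s[, "Pr(>|t|)"]
  )
}

#' Model-level summary of a SALI regression fit
#'
#' @param x A `"sali_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `durbin_watson`,
#'   `residual_skewness`, `df`, `n_years`, `p_value` and `ci_level`.
#' @method glance sali_fit
#' @export
glance.sali_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    durbin_watson = x$durbin_watson,
    residual_skewness = moment_skewness(x$data$residual),
    df = x$df,
    n_years = nrow(x$data),
    p_value = x$p_value,
    ci_level = x$ci_level
  )
}

#' Per-year fitted values, residuals and predictions
#'
#' @param x A `"sali_fit"` object.
#' @param ... Unused.
#' @return Tibble with one row per year: observed deaths, sqrt-scale
#'   observation, fitted value and residual, and the back-transformed
#'   predicted death count.
#' @method augment sali_fit
#' @export
augment.sali_fit <- function(x, ...) {
  d <- x$data
  tibble(
    year = d$year,
    sali = d$sali,
    observed_deaths = d$deaths,
    sqrt_observed = d$sqrt_deaths,
    fitted_sqrt = d$fitted_sqrt,
    residual = d$residual,
    predicted_deaths = predict_deaths(x, d$sali)
  )
}

#' @export
print.sali_fit <- function(x, ...) {
  cat("SALI regression: sqrt(deaths) ~ sali, n =", nrow(x$data),
      "years, df =", x$df, "\n")
  cat(sprintf("  intercept %.6f, slope %.6f (%.0f%% CI %.6f to %.6f)\n",
              x$intercept, x$slope, 100 * x$ci_level,
              x$slope_ci[["lower"]], x$slope_ci[["upper"]]))
  cat(sprintf("  t = %.4f, p = %.3g, r^2 = %.3f, Durbin-Watson = %.3f\n",
              x$t_stat, x$p_value, x$r_squared, x$durbin_watson))
  invisible(x)
}

#' Plot observed and predicted deaths for a fitted model
#'
#' @param object A `"sali_fit"` object.
#' @param ... Unused.
#' @return A ggplot: paired observed and model-predicted annual death
#'   counts by year.
#' @method autoplot sali_fit
#' @export
autoplot.sali_fit <- function(object, ...) {
  a <- augment(object)
  plot_predicted_observed(
    tibble(year = a$year, deaths = a$observed_deaths),
    tibble(year = a$year, predicted = a$predicted_deaths)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
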