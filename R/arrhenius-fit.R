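# The linearized Arrhenius regression ln k = ln A + slope * (1/T), with
# the coefficient statistics reported for pooled toxicokinetic fits
# (SE, CV%, 95% CI, R^2, p), and the uncorrected-vs-mass-corrected
# model comparison.

#' Fit the linearized Arrhenius model to rate records
#'
#' Ordinary least squares of \eqn{y = \ln k} (or \eqn{\ln k^*} under
#' mass correction) on \eqn{x = 1/T}. Solved in closed form on centered
#' x for numerical stability; the intercept is reported on the
#' uncentered scale, so it estimates \eqn{\ln A} and the slope estimates
#' \eqn{-E_A/R} in Kelvin. Standard errors come from the residual
#' variance, the 95% CI uses the t quantile at `n - 2` df, the p-value
#' is the two-sided t-test of slope = 0, and CV% = 100·SE/|estimate|.
#'
#' @param records Tibble of rate records of a *single* rate type with
#'   columns `temperature_K`, `k` and, under mass correction, `mass_kg`.
#' @param use_mass_correction Fit \eqn{\ln(k\,m^{1/4})} instead of
#'   \eqn{\ln k}; requires a mass on every record.
#' @return An object of class `arrhenius_fit` with elements `slope_K`,
#'   `intercept`, `se_slope`, `se_intercept`, `cv_slope_pct`,
#'   `cv_intercept_pct`, `ci95_slope`, `ci95_intercept`, `r_squared`,
#'   `p_value_slope`, `n`, `df`, `residual_variance`, `rate_type`,
#'   `mass_corrected`, and the fitting `data`.
#' @examples
#' rec <- generate_dataset(generator_config(n_uptake = 200, n_elimination = 200,
#'                                          seed = 3))
#' fit_arrhenius(dplyr::filter(rec, rate_type == "uptake"))
#' @export
fit_arrhenius <- function(records, use_mass_correction = FALSE) {
  rt <- unique(records$rate_type)
  if (length(rt) != 1L) {
    stop("`records` must contain a single rate_type; got: ",
         paste(rt, collapse = ", "), ". Filter first.", call. = FALSE)
  }
  if (use_mass_correction && anyNA(records$mass_kg)) {
    bad <- which(is.na(records$mass_kg))
    stop(sprintf(
      "Mass correction requires a body mass on every record; %d record(s) lack one (rows %s%s).",
      length(bad), paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""), call. = FALSE)
  }
  y <- if (use_mass_correction) log(mass_correct(records$k, records$mass_kg))
       else log(records$k)
  x <- 1 / records$temperature_K
  fit <- ols_inverse_temperature(x, y)
  structure(
    c(fit, list(rate_type = rt, mass_corrected = use_mass_correction,
                data = tibble::tibble(inv_T = x, ln_k = y))),
    class = "arrhenius_fit"
  )
}

# closed-form simple OLS on centered x with full coefficient statistics
ols_inverse_temperature <- function(x, y) {
  n <- length(x)
  if (n < 3L) {
    stop(sprintf("Need at least 3 records to fit (have %d).", n),
         call. = FALSE)
  }
  xbar <- mean(x)
  xc <- x - xbar
  sxx <- sum(xc^2)
  if (sxx <= 0) {
    stop("Zero variance in 1/T: all records share one temperature.",
         call. = FALSE)
  }
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * xbar
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  syy <- sum((y - mean(y))^2)
  df <- n - 2L
  s2 <- rss / df
  se_slope <- sqrt(s2 / sxx)
  se_intercept <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  tq <- stats::qt(0.975, df)
  tstat <- slope / se_slope
  list(
    slope_K = slope, intercept = intercept,
    se_slope = se_slope, se_intercept = se_intercept,
    cv_slope_pct = cv_pct(slope, se_slope),
    cv_intercept_pct = cv_pct(intercept, se_intercept),
    ci95_slope = c(slope - tq * se_slope, slope + tq * se_slope),
    ci95_intercept = c(intercept - tq * se_intercept,
                       intercept + tq * se_intercept),
    r_squared = if (syy > 0) 1 - rss / syy else NA_real_,
    p_value_slope = 2 * stats::pt(-abs(tstat), df),
    n = n, df = df, residual_variance = s2, rss = rss
  )
}

#' Coefficient of variation of an estimate, in percent
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s) (the "SD" of a reported coefficient).
#' @return `100 * se / abs(estimate)`.
#' @examples
#' cv_pct(-7888, 1081) # 13.7
#' @export
cv_pct <- function(estimate, se) 100 * se / abs(estimate)

#' t-based confidence interval from printed regression summaries
#'
#' Reconstructs the interval `estimate +/- t(1 - (1-level)/2, n - 2) * se`
#' for a simple-regression coefficient reported only as estimate and SD.
#'
#' @param estimate Point estimate.
#' @param se Standard error.
#' @param n Number of records the regression used (df = n - 2).
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @examples
#' coef_ci(-7888, 1081, 958)
#' @export
coef_ci <- function(estimate, se, n, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, n - 2)
  c(estimate - tq * se, estimate + tq * se)
}

#' Activation energy implied by a fitted Arrhenius slope
#'
#' \eqn{E_A = -\mathrm{slope} \times R} with R = 8.31 J K^-1 mol^-1
#' ([R_GAS]).
#'
#' @param fit An `arrhenius_fit`, an `arrhenius_params`, or a numeric
#'   slope in Kelvin.
#' @return Activation energy in J mol^-1.
#' @examples
#' activation_energy(-10000) # 83100
#' @export
activation_energy <- function(fit) {
  slope <- if (inherits(fit, "arrhenius_fit")) fit$slope_K
           else if (inherits(fit, "arrhenius_params")) fit$slope_K
           else fit
  -slope * R_GAS
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: ln k ~ 1/T  [%s%s, n = %d]\n",
              x$rate_type, if (x$mass_corrected) ", mass-corrected" else "",
              x$n))
  cat(sprintf("  slope     %8.0f +/- %.0f K (CV %.1f%%) [%.0f, %.0f]\n",
              x$slope_K, x$se_slope, x$cv_slope_pct,
              x$ci95_slope[1], x$ci95_slope[2]))
  cat(sprintf("  intercept %8.2f +/- %.2f   (CV %.1f%%) [%.2f, %.2f]\n",
              x$intercept, x$se_intercept, x$cv_intercept_pct,
              x$ci95_intercept[1], x$ci95_intercept[2]))
  cat(sprintf("  R^2 = %.3f, p(slope) = %.3g, E_A = %.3g J/mol\n",
              x$r_squared, x$p_value_slope, activation_energy(x)))
  invisible(x)
}

#' Tidy an Arrhenius fit into a coefficient table
#'
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`slope_K`,
#'   `intercept`): estimate, std.error, cv.pct, conf.low, conf.high,
#'   statistic, p.value.
#' @exportS3Method generics::tidy
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope_K", "intercept"),
    estimate = c(x$slope_K, x$intercept),
    std.error = c(x$se_slope, x$se_intercept),
    cv.pct = c(x$cv_slope_pct, x$cv_intercept_pct),
    conf.low = c(x$ci95_slope[1], x$ci95_intercept[1]),
    conf.high = c(x$ci95_slope[2], x$ci95_intercept[2]),
    statistic = c(x$slope_K / x$se_slope, x$intercept / x$se_intercept),
    p.value = c(x$p_value_slope,
                2 * stats::pt(-abs(x$intercept / x$se_intercept), x$df))
  )
}

#' One-row model summary of an Arrhenius fit
#'
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @return A tibble: r.squared, sigma, p.value, df.residual, nobs,
#'   rate_type, mass_corrected, activation_energy_J_mol.
#' @exportS3Method generics::glance
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma = sqrt(x$residual_variance),
    p.value = x$p_value_slope, df.residual = x$df, nobs = x$n,
    rate_type = x$rate_type, mass_corrected = x$mass_corrected,
    activation_energy_J_mol = activation_energy(x)
  )
}

#' Arrhenius plot of a fit
#'
#' ln k against 1/T with the fitted regression line.
#'
#' @param object An `arrhenius_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.arrhenius_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$inv_T, y = .data$ln_k)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = object$slope_K, intercept = object$intercept,
                         linewidth = 0.8) +
    ggplot2::labs(
      x = expression(1 / T ~ (K^-1)),
      y = if (object$mass_corrected) expression(ln ~ k * "*") else expression(ln ~ k),
      title = sprintf("%s rate constants%s", object$rate_type,
                      if (object$mass_corrected) " (mass-corrected)" else "")
    )
}

#' Compare uncorrected and mass-corrected Arrhenius fits
#'
#' Fits both model variants on the same rate type. The mass-corrected
#' fit uses only records carrying a mass (imputed or observed); the
#' excluded count is reported. The comparison gives the slope-CI overlap
#' and the signed change in coefficient CVs (corrected minus
#' uncorrected), the quantities on which "does mass correction help?"
#' is judged.
#'
#' @param records Tibble of rate records of a single rate type; at least
#'   some must carry `mass_kg`.
#' @return An object of class `model_comparison`: `uncorrected`,
#'   `corrected` (both `arrhenius_fit`), `slope_ci_overlap`,
#'   `delta_cv_slope_pct`, `delta_cv_intercept_pct`, `delta_r_squared`,
#'   `n_excluded_missing_mass`.
#' @export
compare_models <- function(records) {
  has_mass <- !is.na(records$mass_kg)
  if (!any(has_mass)) {
    stop("No record carries a body mass; mass-corrected model cannot be fitted.",
         call. = FALSE)
  }
  uncorrected <- fit_arrhenius(records, use_mass_correction = FALSE)
  corrected <- fit_arrhenius(records[has_mass, , drop = FALSE],
                             use_mass_correction = TRUE)
  overlap <- uncorrected$ci95_slope[1] <= corrected$ci95_slope[2] &&
    corrected$ci95_slope[1] <= uncorrected$ci95_slope[2]
  structure(
    list(
      uncorrected = uncorrected, corrected = corrected,
      slope_ci_overlap = overlap,
      delta_cv_slope_pct = corrected$cv_slope_pct - uncorrected$cv_slope_pct,
      delta_cv_intercept_pct = corrected$cv_intercept_pct -
        uncorrected$cv_intercept_pct,
      delta_r_squared = corrected$r_squared - uncorrected$r_squared,
      n_excluded_missing_mass = sum(!has_mass)
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s): uncorrected vs mass-corrected\n",
              x$uncorrected$rate_type))
  cat(sprintf("  slopes: %.0f vs %.0f K; 95%% CIs %s\n",
              x$uncorrected$slope_K, x$corrected$slope_K,
              if (x$slope_ci_overlap) "overlap" else "do not overlap"))
  cat(sprintf("  delta CV: slope %+.1f%%, intercept %+.1f%%; delta R^2 %+.3f\n",
              x$delta_cv_slope_pct, x$delta_cv_intercept_pct,
              x$delta_r_squared))
  cat(sprintf("  records without mass excluded from corrected fit: %d\n",
              x$n_excluded_missing_mass))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$uncorrected), model = "uncorrected"),
    dplyr::mutate(tidy(x$corrected), model = "mass_corrected")
  ) |>
    dplyr::relocate("model")
}

#' Published pooled Arrhenius regression estimates
#'
#' Coefficient statistics of pooled linearized Arrhenius regressions
#' from a published compilation of toxicokinetic rate constants for
#' organic chemicals in aquatic animals (530 uptake and 958 elimination
#' records spanning crustaceans, molluscs, insects and fish), with and
#' without allometric mass correction. Used as generator defaults, as a
#' consistency check for the package's CV and CI arithmetic, and as a
#' plausibility reference for fitted slopes. `sd` columns are the
#' reported coefficient standard errors; CIs are the reported 95%
#' bounds (slope only; intercept CIs were not reported).
#'
#' @return A tibble with columns `model`, `rate_type`, `n`, `slope_K`,
#'   `slope_sd`, `slope_cv_pct`, `slope_ci_low`, `slope_ci_high`,
#'   `intercept`, `intercept_sd`, `intercept_cv_pct`, `r_squared`.
#' @examples
#' reference_pooled_fits()
#' @export
reference_pooled_fits <- function() {
  tibble::tribble(
    ~model, ~rate_type, ~n, ~slope_K, ~slope_sd, ~slope_cv_pct,
    ~slope_ci_low, ~slope_ci_high, ~intercept, ~intercept_sd,
    ~intercept_cv_pct, ~r_squared,
    "uncorrected", "uptake", 530L, -10000, 1496, 15.0, -12939, -7060,
    40.11, 5.14, 12.8, 0.093,
    "uncorrected", "elimination", 958L, -7888, 1081, 13.7, -10009, -5766,
    25.73, 3.73, 14.5, 0.061,
    "mass_corrected", "uptake", 530L, -10026, 1516, 15.1, -13005, -7046,
    37.65, 5.22, 13.9, 0.091,
    "mass_corrected", "elimination", 958L, -5905, 974, 16.5, -7816, -3994,
    16.83, 3.36, 20.0, 0.043
  )
}

#' Reference physiological Arrhenius slope
#'
#' Average Arrhenius slope reported for whole-organism physiological
#' rates across ectotherms (-7195 K, range -8588 to -4758 K), useful as
#' an external yardstick for fitted toxicokinetic slopes.
#'
#' @return Named list with `slope_K` and `range_K`.
#' @export
reference_physiological_slope <- function() {
  list(slope_K = -7195, range_K = c(-8588, -4758))
}
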