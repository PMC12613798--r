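# One-compartment bioaccumulation experiments: closed-form simulation of
# accumulation/depuration concentration time courses and nonlinear
# least-squares recovery of the uptake and elimination rate constants.

#' Toxicokinetic parameters for one organism--chemical pair
#'
#' @param k_u Uptake rate constant, L kg^-1 d^-1 (> 0).
#' @param k_e Elimination rate constant, d^-1 (> 0).
#' @return An object of class `tk_parameters` with the derived
#'   bioconcentration factor `bcf = k_u / k_e`.
#' @examples
#' tk_parameters(100, 0.5)
#' @export
tk_parameters <- function(k_u, k_e) {
  check_positive(k_u, "k_u")
  check_positive(k_e, "k_e")
  structure(list(k_u = k_u, k_e = k_e, bcf = bcf(k_u, k_e)),
            class = "tk_parameters")
}

#' @export
print.tk_parameters <- function(x, ...) {
  cat(sprintf("<tk_parameters> k_u = %.4g L/kg/d, k_e = %.4g /d, BCF = %.4g L/kg\n",
              x$k_u, x$k_e, x$bcf))
  invisible(x)
}

#' Design of a constant-exposure bioaccumulation experiment
#'
#' Describes an experiment with a constant water concentration up to
#' `t_depuration_start` (days), after which the organism is moved to
#' clean water and depurates. Observation noise is multiplicative
#' lognormal: Gaussian with standard deviation `noise_sigma_ln` on the
#' log concentration.
#'
#' @param c_water Constant exposure concentration (e.g. mg L^-1), > 0.
#' @param t_depuration_start Day the depuration phase starts, > 0.
#' @param sample_times Strictly increasing sampling days >= 0, at least
#'   3 in each phase if the series is to be fitted.
#' @param noise_sigma_ln SD of Gaussian noise on ln(concentration), >= 0.
#' @param seed Optional integer seed making simulated noise reproducible.
#' @return An object of class `exposure_design`.
#' @examples
#' exposure_design(0.01, 7, c(0.5, 1, 2, 4, 7, 8, 10, 14, 21))
#' @export
exposure_design <- function(c_water, t_depuration_start, sample_times,
                            noise_sigma_ln = 0, seed = NULL) {
  check_positive(c_water, "c_water")
  check_positive(t_depuration_start, "t_depuration_start")
  if (length(sample_times) == 0L) {
    stop("`sample_times` must not be empty.", call. = FALSE)
  }
  if (any(sample_times < 0) || is.unsorted(sample_times, strictly = TRUE)) {
    stop("`sample_times` must be non-negative and strictly increasing.",
         call. = FALSE)
  }
  if (noise_sigma_ln < 0) stop("`noise_sigma_ln` must be >= 0.", call. = FALSE)
  structure(
    list(c_water = c_water, t_depuration_start = t_depuration_start,
         sample_times = as.numeric(sample_times),
         noise_sigma_ln = noise_sigma_ln, seed = seed),
    class = "exposure_design"
  )
}

# closed-form one-compartment solution under constant exposure:
# accumulation C(t) = (ku/ke) Cw (1 - e^{-ke t}); depuration decays
# exponentially from the concentration reached at tc
conc_one_compartment <- function(times, k_u, k_e, c_water, t_dep) {
  c_tc <- (k_u / k_e) * c_water * (1 - exp(-k_e * t_dep))
  ifelse(times <= t_dep,
         (k_u / k_e) * c_water * (1 - exp(-k_e * times)),
         c_tc * exp(-k_e * (times - t_dep)))
}

#' Simulate a bioaccumulation experiment
#'
#' Evaluates the one-compartment closed form at the design's sampling
#' times and, when `noise_sigma_ln > 0`, multiplies by lognormal noise
#' (reproducible under the design's `seed`).
#'
#' @param tk A [tk_parameters()] object.
#' @param design An [exposure_design()] object.
#' @return A tibble with columns `time_d`, `c_internal` (mg kg^-1) and
#'   `phase` (`"accumulation"` or `"depuration"`).
#' @examples
#' tk <- tk_parameters(100, 0.5)
#' d <- exposure_design(0.01, 7, c(1, 2, 4, 7, 8, 10, 14))
#' simulate_exposure(tk, d)
#' @export
simulate_exposure <- function(tk, design) {
  stopifnot(inherits(tk, "tk_parameters"), inherits(design, "exposure_design"))
  mu <- conc_one_compartment(design$sample_times, tk$k_u, tk$k_e,
                             design$c_water, design$t_depuration_start)
  if (design$noise_sigma_ln > 0) {
    if (!is.null(design$seed)) set.seed(design$seed)
    mu <- mu * exp(stats::rnorm(length(mu), 0, design$noise_sigma_ln))
  }
  tibble::tibble(
    time_d = design$sample_times,
    c_internal = mu,
    phase = ifelse(design$sample_times <= design$t_depuration_start,
                   "accumulation", "depuration")
  )
}

# initial k_e: negative slope of ln C over the depuration phase
init_k_e <- function(series, t_dep) {
  dep <- series[series$time_d > t_dep, , drop = FALSE]
  if (nrow(dep) < 2L) return(NA_real_)
  fit <- stats::coef(stats::lm(log(c_internal) ~ time_d, data = dep))
  max(-unname(fit[2]), 1e-6)
}

#' Estimate uptake and elimination rate constants from a time course
#'
#' Fits the one-compartment accumulation/depuration model to an observed
#' concentration series by nonlinear least squares. By default the fit is
#' on ln(concentration), which is homoscedastic under multiplicative
#' lognormal noise; set `ln_scale = FALSE` for natural-scale residuals.
#' Rate constants are optimized on the log-parameter scale so estimates
#' stay positive; standard errors are mapped back by the delta method.
#' Initial values come from the log-linear depuration slope (k_e) and the
#' last accumulation-phase concentration (k_u).
#'
#' @param series Tibble with columns `time_d`, `c_internal` (all > 0),
#'   e.g. from [simulate_exposure()].
#' @param c_water Exposure water concentration.
#' @param t_depuration_start Day the depuration phase started.
#' @param ln_scale Fit in log-concentration space (default `TRUE`).
#' @return One-row tibble: `k_u`, `k_e`, `bcf`, `se_k_u`, `se_k_e`,
#'   `converged`, `n_obs`. A failed optimization is reported with
#'   `converged = FALSE`, never silently.
#' @examples
#' tk <- tk_parameters(100, 0.5)
#' d <- exposure_design(0.01, 7, c(0.5, 1, 2, 4, 6, 7, 8, 10, 14, 21))
#' estimate_rate_constants(simulate_exposure(tk, d), 0.01, 7)
#' @export
estimate_rate_constants <- function(series, c_water, t_depuration_start,
                                    ln_scale = TRUE) {
  if (!all(c("time_d", "c_internal") %in% names(series))) {
    stop("`series` needs columns `time_d` and `c_internal`.", call. = FALSE)
  }
  if (any(series$c_internal <= 0)) {
    stop("Concentrations must be positive.", call. = FALSE)
  }
  n_acc <- sum(series$time_d <= t_depuration_start)
  n_dep <- sum(series$time_d > t_depuration_start)
  if (n_acc < 3L || n_dep < 3L) {
    stop(sprintf(
      "Need >= 3 samples per phase to estimate two rate constants (have %d accumulation, %d depuration).",
      n_acc, n_dep), call. = FALSE)
  }

  ke0 <- init_k_e(series, t_depuration_start)
  acc <- series[series$time_d <= t_depuration_start, , drop = FALSE]
  c_last <- acc$c_internal[which.max(acc$time_d)]
  t_last <- max(acc$time_d)
  ku0 <- c_last * ke0 / (c_water * (1 - exp(-ke0 * t_last)))
  start <- list(lku = log(max(ku0, 1e-8)), lke = log(ke0))

  df <- data.frame(t = series$time_d, c = series$c_internal)
  model_fun <- function(lku, lke, t) {
    conc_one_compartment(t, exp(lku), exp(lke), c_water, t_depuration_start)
  }
  fml <- if (ln_scale) {
    log(c) ~ log(model_fun(lku, lke, t))
  } else {
    c ~ model_fun(lku, lke, t)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(tibble::tibble(k_u = NA_real_, k_e = NA_real_, bcf = NA_real_,
                          se_k_u = NA_real_, se_k_e = NA_real_,
                          converged = FALSE, n_obs = nrow(series)))
  }
  est <- stats::coef(fit)
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) c(lku = NA_real_, lke = NA_real_))
  k_u <- exp(est[["lku"]])
  k_e <- exp(est[["lke"]])
  tibble::tibble(
    k_u = k_u, k_e = k_e, bcf = k_u / k_e,
    se_k_u = k_u * unname(se_log[["lku"]]),   # delta method from log scale
    se_k_e = k_e * unname(se_log[["lke"]]),
    converged = fit$convInfo$isConv %||% TRUE,
    n_obs = nrow(series)
  )
}

#' Plot a concentration time course with its fitted curve
#'
#' @param series Tibble from [simulate_exposure()] (or matching columns).
#' @param tk Optional [tk_parameters()] to overlay the closed-form curve.
#' @param c_water,t_depuration_start Experiment constants, needed when
#'   `tk` is supplied.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(series, tk = NULL, c_water = NULL,
                            t_depuration_start = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_d,
                                            y = .data$c_internal)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$phase)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (d)", y = expression(C[internal]~(mg~kg^-1)))
  if (!is.null(tk)) {
    grid <- tibble::tibble(
      time_d = seq(min(series$time_d), max(series$time_d), length.out = 200)
    )
    grid$c_internal <- conc_one_compartment(grid$time_d, tk$k_u, tk$k_e,
                                            c_water, t_depuration_start)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}
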