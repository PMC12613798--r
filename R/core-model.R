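# Closed-form relations: Arrhenius temperature scaling, allometric
# quarter-power mass normalization, one-compartment bioconcentration factor.

#' Ideal gas constant used throughout (J K^-1 mol^-1)
#'
#' The value carried through activation-energy conversions. The two-decimal
#' convention (8.31 rather than 8.3145) follows common ecotoxicological
#' usage; the difference is far below the uncertainty of any fitted slope.
#' @export
R_GAS <- 8.31

#' Arrhenius parameters for one toxicokinetic process
#'
#' Bundles the intercept and slope of the linearized Arrhenius relation
#' \eqn{\ln k = \ln A + s / T} for either uptake or elimination.
#' `slope_K` has units Kelvin and equals \eqn{-E_A/R}; it is negative for
#' any process with positive activation energy, so rate constants rise
#' with temperature. `ln_A` is the natural log of the frequency factor
#' (log of L kg\eqn{^{-1}} d\eqn{^{-1}} for uptake, of d\eqn{^{-1}} for
#' elimination).
#'
#' @param ln_A Natural log of the frequency factor (dimensionless).
#' @param slope_K Arrhenius slope in Kelvin (\eqn{-E_A/R}).
#' @param process `"uptake"` or `"elimination"`.
#' @return An object of class `arrhenius_params`.
#' @examples
#' arrhenius_params(40.11, -10000, "uptake")
#' @export
arrhenius_params <- function(ln_A, slope_K, process = c("uptake", "elimination")) {
  process <- match.arg(process)
  if (!is.numeric(ln_A) || length(ln_A) != 1L || !is.finite(ln_A)) {
    stop("`ln_A` must be a single finite number.", call. = FALSE)
  }
  if (!is.numeric(slope_K) || length(slope_K) != 1L || !is.finite(slope_K)) {
    stop("`slope_K` must be a single finite number.", call. = FALSE)
  }
  structure(
    list(ln_A = as.numeric(ln_A), slope_K = as.numeric(slope_K), process = process),
    class = "arrhenius_params"
  )
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_params> %s: ln A = %.4g, slope = %.4g K (E_A = %.3g J/mol)\n",
    x$process, x$ln_A, x$slope_K, -x$slope_K * R_GAS
  ))
  invisible(x)
}

#' Evaluate the Arrhenius relation
#'
#' Computes \eqn{k = \exp(\ln A + s/T)}, the rate constant predicted at
#' absolute temperature `temperature_K`. Strictly increasing in
#' temperature whenever the slope is negative.
#'
#' @param params An [arrhenius_params()] object.
#' @param temperature_K Temperature(s) in Kelvin, all positive.
#' @return Numeric vector of rate constants (same units as the frequency
#'   factor).
#' @examples
#' p <- arrhenius_params(40.11, -10000, "uptake")
#' arrhenius_rate(p, 293.15)
#' @export
arrhenius_rate <- function(params, temperature_K) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (!is.numeric(temperature_K) || any(!is.finite(temperature_K)) ||
      any(temperature_K <= 0)) {
    stop("`temperature_K` must be positive and finite (Kelvin).", call. = FALSE)
  }
  exp(params$ln_A + params$slope_K / temperature_K)
}

#' Allometric quarter-power mass normalization
#'
#' Rate constants of ectotherms scale approximately with body mass to the
#' power \eqn{-1/4}. `mass_correct()` removes that dependence,
#' re-expressing a rate constant as the coefficient for a 1 kg organism:
#' \eqn{k^* = k \, m^{1/4}} (equivalently, division by \eqn{m^{-1/4}}).
#' `mass_uncorrect()` is the exact inverse, \eqn{k = k^* m^{-1/4}}.
#'
#' @param k Positive rate constant(s).
#' @param k_star Positive mass-corrected rate constant(s).
#' @param mass_kg Positive body mass(es) in kg.
#' @return Numeric vector; `mass_correct()` returns k in units
#'   L kg\eqn{^{-1}} kg\eqn{^{1/4}} d\eqn{^{-1}} (uptake) or
#'   kg\eqn{^{1/4}} d\eqn{^{-1}} (elimination).
#' @examples
#' mass_correct(5, 1e-4)     # 0.5
#' mass_uncorrect(0.5, 1e-4) # back to 5
#' @export
mass_correct <- function(k, mass_kg) {
  check_positive(k, "k")
  check_positive(mass_kg, "mass_kg")
  k * mass_kg^(1 / 4)
}

#' @rdname mass_correct
#' @export
mass_uncorrect <- function(k_star, mass_kg) {
  check_positive(k_star, "k_star")
  check_positive(mass_kg, "mass_kg")
  k_star * mass_kg^(-1 / 4)
}

#' Steady-state bioconcentration factor
#'
#' In a one-compartment model with uptake from water at rate `k_u`
#' (L kg^-1 d^-1) and first-order elimination at rate `k_e` (d^-1), the
#' steady-state internal:water concentration ratio is
#' \eqn{BCF = k_u / k_e} (L kg^-1). If uptake and elimination share the
#' same Arrhenius slope, the temperature dependence cancels in this ratio
#' and the BCF is temperature-independent.
#'
#' @param k_u Positive uptake rate constant(s), L kg^-1 d^-1.
#' @param k_e Positive elimination rate constant(s), d^-1.
#' @return BCF in L kg^-1.
#' @examples
#' bcf(100, 0.5) # 200
#' @export
bcf <- function(k_u, k_e) {
  check_positive(k_u, "k_u")
  check_positive(k_e, "k_e")
  k_u / k_e
}

#' Temperature unit conversion
#'
#' @param temp_c Temperature in degrees Celsius.
#' @param temp_k Temperature in Kelvin.
#' @return Converted temperature.
#' @examples
#' celsius_to_kelvin(20) # 293.15
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k) temp_k - 273.15

# shared validator: strictly positive finite numeric
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite.", name), call. = FALSE)
  }
  invisible(x)
}

# round to nearest integer with x.5 going away from zero (the rule used
# when collapsing duplicate temperatures; base round() rounds half to even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)
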