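# Extraction thermodynamics: equilibrium constant, Van't Hoff regression,
# and the Gibbs energy series.
#
#   Keq     = Cs / (Cmax - Cs)          extracted over unextracted at equilibrium
#   ln Keq  = -dH/(R T) + dS/R          Van't Hoff line in 1/T
#   dG(T)   = dH - T dS                 Gibbs-Helmholtz identity
#   dG(T)   = -R T ln Keq               isotherm form
#
# Temperatures are converted to kelvin with the package-wide +273 offset.

#' Extraction equilibrium constant
#'
#' Keq = Cs / (Cmax - Cs): the ratio of the extracted quantity at
#' equilibrium to the quantity left in the matrix, where `c_max` is the
#' total extractable content under exhaustive extraction.
#'
#' @param cs Saturation concentration at this temperature (0 < cs < c_max).
#' @param c_max Maximum extractable concentration (same units).
#' @return The dimensionless equilibrium constant.
#' @export
#' @examples
#' equilibrium_constant(80, 100) # 4
equilibrium_constant <- function(cs, c_max) {
  if (any(cs <= 0)) stop_pk("`cs` must be > 0", "phenolkin_validation_error")
  if (any(cs >= c_max)) {
    stop_pk("`cs` must be strictly below `c_max` (Keq undefined at complete extraction)",
            "phenolkin_domain_error")
  }
  cs / (c_max - cs)
}

#' Van't Hoff regression for extraction enthalpy and entropy
#'
#' OLS of ln Keq on 1/T: dH = -slope * R_gas, dS = intercept * R_gas.
#'
#' @param temperature_K Absolute temperatures in kelvin (>= 2 distinct).
#' @param keq Equilibrium constants (> 0), same length.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return A list of class `vant_hoff_fit`: `delta_h` (J/mol), `delta_s`
#'   (J/(mol K)), `quality` (ln Keq scale).
#' @export
vant_hoff_fit <- function(temperature_K, keq, gas_constant = GAS_CONSTANT) {
  temperature_K <- as.numeric(temperature_K)
  keq <- as.numeric(keq)
  if (length(temperature_K) != length(keq)) {
    stop_pk("`temperature_K` and `keq` must have the same length",
            "phenolkin_validation_error")
  }
  if (any(keq <= 0)) stop_pk("all Keq must be > 0", "phenolkin_validation_error")
  if (any(temperature_K <= 0)) {
    stop_pk("absolute temperatures must be > 0", "phenolkin_validation_error")
  }
  if (length(unique(temperature_K)) < 2) {
    stop_pk("need >= 2 distinct temperatures for a Van't Hoff fit",
            "phenolkin_validation_error")
  }
  inv_T <- 1 / temperature_K
  lnk <- log(keq)
  fit <- lm(lnk ~ inv_T)
  quality <- if (length(lnk) > 2) {
    goodness_of_fit(lnk, unname(predict(fit)))
  } else {
    structure(list(r_squared = 1, mse = 0, rmse = 0, n_points = 2L),
              class = "fit_quality")
  }
  structure(
    list(delta_h = -unname(coef(fit)[2]) * gas_constant,
         delta_s = unname(coef(fit)[1]) * gas_constant,
         quality = quality),
    class = "vant_hoff_fit"
  )
}

#' Gibbs energy from enthalpy and entropy
#'
#' dG = dH - T dS (all in J/mol and J/(mol K)); vectorized over
#' temperature.
#'
#' @param delta_h Enthalpy change, J/mol.
#' @param delta_s Entropy change, J/(mol K).
#' @param temperature_K Absolute temperature, kelvin (> 0).
#' @return Gibbs energy change in J/mol.
#' @export
#' @examples
#' gibbs_energy(3815.1, 32.8216, 303) / 1000 # -6.1299 kJ/mol
gibbs_energy <- function(delta_h, delta_s, temperature_K) {
  if (any(temperature_K <= 0)) {
    stop_pk("absolute temperatures must be > 0", "phenolkin_validation_error")
  }
  delta_h - temperature_K * delta_s
}

#' Gibbs energy from the equilibrium constant (isotherm form)
#'
#' dG = -R T ln Keq.
#'
#' @param keq Equilibrium constant (> 0).
#' @param temperature_K Absolute temperature, kelvin (> 0).
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return Gibbs energy change in J/mol.
#' @export
gibbs_from_keq <- function(keq, temperature_K, gas_constant = GAS_CONSTANT) {
  if (any(keq <= 0)) stop_pk("`keq` must be > 0", "phenolkin_domain_error")
  if (any(temperature_K <= 0)) {
    stop_pk("absolute temperatures must be > 0", "phenolkin_validation_error")
  }
  -gas_constant * temperature_K * log(keq)
}

#' Recover enthalpy and entropy from a Gibbs energy series
#'
#' OLS of dG on T: by dG = dH - T dS, the intercept estimates dH and the
#' negated slope estimates dS. Useful for checking the internal
#' consistency of a reported thermodynamic table.
#'
#' @param delta_g Gibbs energies, J/mol.
#' @param temperature_K Absolute temperatures, kelvin (>= 2 distinct).
#' @return A list with `delta_h` (J/mol), `delta_s` (J/(mol K)), `quality`.
#' @export
gibbs_line_fit <- function(delta_g, temperature_K) {
  if (length(delta_g) != length(temperature_K) ||
      length(unique(temperature_K)) < 2) {
    stop_pk("need >= 2 distinct temperatures with matching dG values",
            "phenolkin_validation_error")
  }
  fit <- lm(delta_g ~ temperature_K)
  quality <- if (length(delta_g) > 2) {
    goodness_of_fit(delta_g, unname(predict(fit)))
  } else {
    structure(list(r_squared = 1, mse = 0, rmse = 0, n_points = 2L),
              class = "fit_quality")
  }
  list(delta_h = unname(coef(fit)[1]), delta_s = -unname(coef(fit)[2]),
       quality = quality)
}

#' Full thermodynamic chain from saturation concentrations
#'
#' Computes Keq at each temperature from the fitted saturation
#' concentration and a global `c_max`, fits the Van't Hoff line, and
#' evaluates the Gibbs energy series dG(T) = dH - T dS at the same
#' temperatures.
#'
#' @param temperature Temperatures in degrees Celsius.
#' @param cs Saturation concentrations (mg GAE/g d.w.), one per
#'   temperature.
#' @param c_max Maximum extractable concentration (single global value).
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return An object of class `thermo_result`: `delta_h`, `delta_s`,
#'   `keq_series` and `delta_g_series` data frames, `c_max`, `quality`.
#' @export
thermo_chain <- function(temperature, cs, c_max, gas_constant = GAS_CONSTANT) {
  if (length(temperature) != length(cs)) {
    stop_pk("`temperature` and `cs` must have the same length",
            "phenolkin_validation_error")
  }
  T_K <- celsius_to_kelvin(temperature)
  keq <- equilibrium_constant(cs, c_max)
  vh <- vant_hoff_fit(T_K, keq, gas_constant)
  structure(
    list(delta_h = vh$delta_h, delta_s = vh$delta_s,
         keq_series = data.frame(temperature_K = T_K, keq = keq),
         delta_g_series = data.frame(
           temperature_K = T_K,
           delta_g = gibbs_energy(vh$delta_h, vh$delta_s, T_K)),
         c_max = c_max, quality = vh$quality),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.4g J/mol, dS = %.4g J/(mol K), dG in [%.4g, %.4g] J/mol\n",
              x$delta_h, x$delta_s,
              min(x$delta_g_series$delta_g), max(x$delta_g_series$delta_g)))
  invisible(x)
}
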