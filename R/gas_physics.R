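#' Henry solubility of CO2 or CH4 in fresh water
#'
#' Temperature-dependent solubility used to convert a partial pressure into a
#' dissolved concentration. CO2 uses the classic zero-salinity Weiss-type fit
#' (`ln K0 = a1 + a2 (100/T) + a3 ln(T/100)`, K0 in mol L-1 atm-1); CH4 uses
#' the corresponding Bunsen-coefficient fit divided by the STP molar volume.
#' Both coefficient sets live in [flux_constants()] and can be overridden.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param water_temp_c Water temperature, degC, in \[-1, 40\].
#' @param constants Constants table, see [flux_constants()].
#' @return Solubility in mol m-3 atm-1 (positive, decreasing with
#'   temperature).
#' @examples
#' henry_constant("CO2", 25)   # ~ 34 mol m-3 atm-1
#' henry_constant("CH4", 20)   # ~ 1.6 mol m-3 atm-1
#' @export
henry_constant <- function(gas, water_temp_c, constants = flux_constants()) {
  gas <- match_gas(gas)
  if (any(water_temp_c < -1 | water_temp_c > 40)) {
    stop("water_temp_c outside the calibrated range [-1, 40] degC",
         call. = FALSE)
  }
  tk <- water_temp_c + 273.15
  if (gas == "CO2") {
    a <- constants$henry_co2
    k0 <- exp(a[["a1"]] + a[["a2"]] * (100 / tk) + a[["a3"]] * log(tk / 100))
    1000 * k0                                   # mol L-1 -> mol m-3
  } else {
    a <- constants$henry_ch4
    bunsen <- exp(a[["a1"]] + a[["a2"]] * (100 / tk) +
                    a[["a3"]] * log(tk / 100))  # L gas L-1 water atm-1
    1000 * bunsen / constants$molar_volume_l
  }
}

#' Schmidt number of CO2 or CH4 in fresh water
#'
#' Fourth-order polynomial in temperature (freshwater coefficients). The
#' k600 convention is anchored here: Sc(CO2, 20 degC) is ~600.
#'
#' @inheritParams henry_constant
#' @param water_temp_c Water temperature, degC, in \[0, 35\].
#' @return Dimensionless Schmidt number (positive, decreasing with
#'   temperature).
#' @examples
#' schmidt_number("CO2", 20)  # ~ 600
#' @export
schmidt_number <- function(gas, water_temp_c, constants = flux_constants()) {
  gas <- match_gas(gas)
  if (any(water_temp_c < 0 | water_temp_c > 35)) {
    stop("water_temp_c outside the calibrated range [0, 35] degC",
         call. = FALSE)
  }
  a <- constants$schmidt_coef[[gas]]
  t <- water_temp_c
  a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3 + a[5] * t^4
}

#' Wind-based gas transfer velocity: Cole & Caraco model
#'
#' `k600 = 2.07 + 0.215 U10^1.7`, with U10 the (monthly mean) wind speed at
#' 10 m height. Returns the k600 in the units the parameterization was
#' published in (cm h-1); use [scale_k_to_gas()] to convert to a gas- and
#' temperature-specific velocity in m d-1.
#'
#' @param u10_m_s Wind speed at 10 m, m s-1 (non-negative).
#' @return k600 in cm h-1; equals 2.07 at zero wind.
#' @examples
#' k600_cole_caraco(0)
#' k600_cole_caraco(5)
#' @export
k600_cole_caraco <- function(u10_m_s) {
  if (any(u10_m_s < 0)) stop("u10_m_s must be non-negative", call. = FALSE)
  2.07 + 0.215 * u10_m_s^1.7
}

#' Wind-based gas transfer velocity: Vachon & Prairie model
#'
#' `k600 = 2.51 + 1.48 U10 + 0.39 U10 log10(LA)`, where LA is lake area in
#' km2; larger lakes have longer wind fetch and hence faster exchange at a
#' given wind. At zero wind both wind terms vanish and the intercept 2.51
#' cm h-1 is returned for any lake area.
#'
#' @inheritParams k600_cole_caraco
#' @param lake_area_km2 Lake area, km2 (positive).
#' @return k600 in cm h-1.
#' @examples
#' k600_vachon_prairie(0, 0.5)
#' k600_vachon_prairie(3, 1)
#' @export
k600_vachon_prairie <- function(u10_m_s, lake_area_km2) {
  if (any(u10_m_s < 0)) stop("u10_m_s must be non-negative", call. = FALSE)
  if (any(lake_area_km2 <= 0)) {
    stop("lake_area_km2 must be positive", call. = FALSE)
  }
  2.51 + 1.48 * u10_m_s + 0.39 * u10_m_s * log10(lake_area_km2)
}

#' Rescale a k600 to an arbitrary Schmidt number
#'
#' Core of the Schmidt-number convention: `k = k600 (Sc/600)^n`, with n = -1/2
#' for wavy/turbulent surfaces (default) or -2/3 for smooth ones. Input is in
#' the wind models' native cm h-1; output is converted to the package's
#' canonical m d-1.
#'
#' @param k600_cm_h Gas transfer velocity normalized to Sc = 600, cm h-1.
#' @param sc Schmidt number of the target gas at in-situ temperature.
#' @param exponent Schmidt exponent n.
#' @return Gas transfer velocity in m d-1.
#' @examples
#' scale_k600(2.07, 600)  # pure unit conversion: 2.07 * 24/100
#' @export
scale_k600 <- function(k600_cm_h, sc, exponent = -0.5) {
  if (any(k600_cm_h < 0)) stop("k600_cm_h must be non-negative", call. = FALSE)
  if (any(sc <= 0)) stop("Schmidt number must be positive", call. = FALSE)
  k600_cm_h * (sc / 600)^exponent * (24 / 100)
}

#' Gas transfer velocity for a specific gas and temperature
#'
#' Convenience wrapper composing [schmidt_number()] and [scale_k600()].
#'
#' @inheritParams henry_constant
#' @param k600_cm_h k600 in cm h-1 (e.g. from a wind model).
#' @param exponent Schmidt exponent; default from `constants$sc_exponent`.
#' @return k for `gas` at `water_temp_c`, in m d-1.
#' @examples
#' scale_k_to_gas(k600_cole_caraco(3), "CH4", 15)
#' @export
scale_k_to_gas <- function(k600_cm_h, gas, water_temp_c,
                           exponent = NULL,
                           constants = flux_constants()) {
  if (is.null(exponent)) exponent <- constants$sc_exponent
  sc <- schmidt_number(gas, water_temp_c, constants)
  scale_k600(k600_cm_h, sc, exponent)
}

#' Dissolved concentration at a given mixing ratio
#'
#' Converts a mixing ratio (ppmv) and ambient pressure into a dissolved
#' concentration via Henry's law: partial pressure = mixing ratio x pressure
#' (in atm), never assuming 1 atm.
#'
#' @inheritParams henry_constant
#' @param ppmv Mixing ratio, ppmv.
#' @param pressure_kpa Ambient pressure, kPa.
#' @return Concentration in mol m-3.
#' @examples
#' gas_concentration("CO2", 1044, 101.325, 15)
#' @export
gas_concentration <- function(gas, ppmv, pressure_kpa, water_temp_c,
                              constants = flux_constants()) {
  p_atm <- pressure_kpa / constants$std_pressure_kpa
  henry_constant(gas, water_temp_c, constants) * ppmv * 1e-6 * p_atm
}

#' Air-water equilibrium concentration
#'
#' Dissolved concentration a lake would hold if it were at equilibrium with
#' the reference atmosphere (404.2 ppmv CO2 / 1.8 ppmv CH4 by default).
#'
#' @inheritParams henry_constant
#' @param atm An [atmosphere()] object.
#' @return Equilibrium concentration in mol m-3.
#' @examples
#' equilibrium_concentration("CH4", atmosphere(), 15)
#' @export
equilibrium_concentration <- function(gas, atm, water_temp_c,
                                      constants = flux_constants()) {
  gas <- match_gas(gas)
  ppmv <- if (gas == "CO2") atm$pco2_eq_ppmv else atm$pch4_eq_ppmv
  gas_concentration(gas, ppmv, atm$pressure_kpa, water_temp_c, constants)
}

#' Diffusive gas flux across the air-water interface
#'
#' `F = k (c_water - c_eq) x 12.01`, expressed in grams of carbon (both CO2
#' and CH4 carry one C atom per molecule). Positive values are outward flux
#' from the lake into the atmosphere; supersaturated water gives positive
#' flux, undersaturated water gives uptake.
#'
#' @param k_m_d Gas transfer velocity, m d-1 (non-negative).
#' @param c_water Dissolved concentration, mol m-3.
#' @param c_eq Equilibrium concentration, mol m-3.
#' @param constants Constants table.
#' @return Flux in g C m-2 d-1.
#' @examples
#' diffusive_flux(0.5, 0.04, 0.02)
#' @export
diffusive_flux <- function(k_m_d, c_water, c_eq,
                           constants = flux_constants()) {
  if (any(k_m_d < 0)) stop("k_m_d must be non-negative", call. = FALSE)
  k_m_d * (c_water - c_eq) * constants$molar_mass_c
}
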