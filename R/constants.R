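#' Physical constants and default parameters
#'
#' One versioned table holding every constant the pipeline uses: atmospheric
#' equilibrium mixing ratios, the CH4 global warming potential, molar masses,
#' solubility and Schmidt-number coefficients, QC thresholds and numerical
#' guards. All downstream functions take their defaults from here, so a single
#' override (in code or from a YAML file) changes the whole pipeline
#' consistently.
#'
#' @param overrides Named list of values to override, or the path to a YAML
#'   file containing such a list. Nested lists (e.g. `qc`) are merged
#'   element-wise. Unknown keys are an error: silent typos in a config must
#'   not produce a silently different analysis.
#'
#' @return A named list of constants with class `"flux_constants"`. Notable
#'   entries:
#'   \describe{
#'     \item{pco2_eq_ppmv, pch4_eq_ppmv}{Air equilibrium mixing ratios,
#'       404.2 and 1.8 ppmv (2016 Mauna Loa annual means).}
#'     \item{gwp100_ch4}{100-year global warming potential of CH4 (28).}
#'     \item{sc_exponent}{Schmidt-number exponent n in k = k600 (Sc/600)^n;
#'       -1/2 for wavy lake surfaces, -2/3 for smooth ones.}
#'     \item{schmidt_coef}{Freshwater 4th-order Sc(T) polynomial coefficients
#'       per gas.}
#'     \item{henry_co2, henry_ch4}{Coefficients of the zero-salinity
#'       solubility fits (Weiss-type for CO2; Bunsen-coefficient fit for
#'       CH4).}
#'     \item{qc}{Chamber QC thresholds, see [qc_classify()].}
#'     \item{k_floor_mol_m3}{Minimum |c_water - c_eq| below which a
#'       chamber-derived gas transfer velocity is considered undefined.}
#'   }
#'
#' @examples
#' cst <- flux_constants()
#' cst$pco2_eq_ppmv
#' flux_constants(list(gwp100_ch4 = 34))$gwp100_ch4
#' @export
flux_constants <- function(overrides = NULL) {
  cst <- list(
    version = "thawflux-constants-1",
    # atmosphere
    pco2_eq_ppmv = 404.2,
    pch4_eq_ppmv = 1.8,
    std_pressure_kpa = 101.325,
    # gases
    molar_mass_c = 12.01,
    molar_mass_co2 = 44.01,
    molar_mass_ch4 = 16.04,
    gwp100_ch4 = 28,
    r_gas = 8.314,          # J mol-1 K-1
    # gas exchange
    sc_reference = 600,
    sc_exponent = -0.5,
    # Sc(T) = a0 + a1 T + a2 T^2 + a3 T^3 + a4 T^4, T in degC, freshwater
    schmidt_coef = list(
      CO2 = c(1923.6, -125.06, 4.3773, -0.085681, 0.00070284),
      CH4 = c(1909.4, -120.78, 4.1555, -0.080578, 0.00065777)
    ),
    # ln K0 [mol L-1 atm-1] = a1 + a2 (100/T) + a3 ln(T/100), T in K
    henry_co2 = c(a1 = -58.0931, a2 = 90.5069, a3 = 22.2940),
    # ln beta [L L-1 atm-1] = a1 + a2 (100/T) + a3 ln(T/100), T in K
    henry_ch4 = c(a1 = -67.1962, a2 = 99.1624, a3 = 27.9015),
    molar_volume_l = 22.414,  # ideal gas at STP, converts Bunsen to molar
    # chamber QC
    qc = list(
      r2_single = 0.75,          # r2 strictly above this -> retained_linear
      r2_replicate_mean = 0.55,  # replicate-mean retention threshold
      uptake_tol = 0.05          # "close to" equilibrium tolerance (fraction)
    ),
    k_floor_mol_m3 = 5e-4
  )
  if (is.null(overrides)) {
    class(cst) <- "flux_constants"
    return(cst)
  }
  if (is.character(overrides) && length(overrides) == 1L) {
    overrides <- yaml::read_yaml(overrides)
  }
  stopifnot(is.list(overrides))
  cst <- merge_constants(cst, overrides, path = "constants")
  class(cst) <- "flux_constants"
  cst
}

# Recursive modifyList that refuses unknown keys.
merge_constants <- function(base, over, path) {
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) {
    stop("all constant overrides must be named (at ", path, ")", call. = FALSE)
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown) > 0L) {
    stop("unknown constant key(s) at ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in nm) {
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- merge_constants(base[[k]], over[[k]],
                                   path = paste0(path, "$", k))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Reference atmosphere
#'
#' Bundles the air-side equilibrium mixing ratios and the ambient pressure
#' used to convert mixing ratios into partial pressures. The defaults are the
#' 2016 global annual means (404.2 ppmv CO2, 1.8 ppmv CH4) at standard
#' pressure; field campaigns should pass the measured barometric pressure.
#'
#' @param pco2_eq_ppmv Air CO2 mixing ratio at equilibrium, ppmv.
#' @param pch4_eq_ppmv Air CH4 mixing ratio at equilibrium, ppmv.
#' @param pressure_kpa Ambient pressure, kPa; must lie in (50, 110).
#' @return A list with class `"atmosphere"`.
#' @examples
#' atmosphere()
#' atmosphere(pressure_kpa = 99.8)
#' @export
atmosphere <- function(pco2_eq_ppmv = 404.2, pch4_eq_ppmv = 1.8,
                       pressure_kpa = 101.325) {
  if (pco2_eq_ppmv <= 0 || pch4_eq_ppmv <= 0) {
    stop("equilibrium mixing ratios must be positive", call. = FALSE)
  }
  if (pressure_kpa <= 50 || pressure_kpa >= 110) {
    stop("pressure_kpa must lie in (50, 110) kPa", call. = FALSE)
  }
  structure(list(pco2_eq_ppmv = pco2_eq_ppmv,
                 pch4_eq_ppmv = pch4_eq_ppmv,
                 pressure_kpa = pressure_kpa),
            class = "atmosphere")
}

# internal: validated gas name
match_gas <- function(gas) {
  match.arg(gas, c("CO2", "CH4"))
}
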