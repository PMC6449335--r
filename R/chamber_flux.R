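#' Fit the CO2 accumulation rate of one chamber deployment
#'
#' Ordinary least squares of chamber CO2 mixing ratio against time over the
#' first 1-2.5 h of the record (floating chambers are only trusted while the
#' headspace is far from equilibrium). The window defaults to the longest
#' available stretch up to `window_h`.
#'
#' @param t_s Seconds since deployment start; strictly increasing, starting
#'   at 0, nominal cadence 300 s.
#' @param co2_ppm Chamber CO2 mixing ratio series, ppm, same length as `t_s`.
#' @param window_h Regression window in hours, in \[1, 2.5\].
#' @return A list with class `"slope_fit"`: `slope_ppm_s`, `intercept_ppm`,
#'   `r2`, `n_points`, `window_h` (hours actually used). A zero-variance
#'   response yields slope 0 and `r2 = 0` (degenerate series should fail QC
#'   cleanly, not propagate NaN).
#' @examples
#' t <- seq(0, 5400, by = 300)
#' fit_accumulation(t, 400 + 0.01 * t)
#' @export
fit_accumulation <- function(t_s, co2_ppm, window_h = 2.5) {
  if (length(t_s) != length(co2_ppm)) {
    stop("t_s and co2_ppm must have the same length", call. = FALSE)
  }
  if (length(t_s) < 3L || any(diff(t_s) <= 0) || t_s[1] != 0) {
    stop("t_s must start at 0 and be strictly increasing with >= 3 points",
         call. = FALSE)
  }
  if (window_h < 1 || window_h > 2.5) {
    stop("window_h must lie in [1, 2.5] hours", call. = FALSE)
  }
  keep <- t_s <= window_h * 3600
  if (sum(keep) < 3L) {
    stop("fewer than 3 points inside the regression window", call. = FALSE)
  }
  t <- t_s[keep]
  y <- co2_ppm[keep]
  fit <- stats::lm(y ~ t)
  cf <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope_ppm_s = unname(cf[2]),
                 intercept_ppm = unname(cf[1]),
                 r2 = r2,
                 n_points = length(t),
                 window_h = max(t) / 3600),
            class = "slope_fit")
}

#' QC-classify the chamber fits of one lake-season
#'
#' Implements the retention rules of the chamber protocol:
#' \itemize{
#'   \item positive slope with `r2 > 0.75` -> `retained_linear`;
#'   \item positive slope with lower r2 -> `retained_by_replicates` if the
#'     mean r2 across the lake-season's replicate chambers is >= 0.55,
#'     otherwise `discarded_nonlinear`;
#'   \item negative (or zero) slope, interpreted as CO2 uptake ->
#'     `retained_uptake` if the lake's water pCO2 is close to or below the
#'     atmospheric equilibrium (within `uptake_tol`, default 5%, of 404.2
#'     ppmv), otherwise `discarded_uptake_conflict` (uptake from visibly
#'     supersaturated water is physically inconsistent and dropped).
#' }
#'
#' @param slopes Numeric vector of fitted slopes (ppm s-1), one per chamber.
#' @param r2 Numeric vector of fit r2 values, same length.
#' @param pco2_water_ppmv The lake's water pCO2 for this season, ppmv.
#' @param atm An [atmosphere()] object (supplies the 404.2 ppmv reference).
#' @param qc List of thresholds (`r2_single`, `r2_replicate_mean`,
#'   `uptake_tol`), default from [flux_constants()].
#' @return Character vector of verdicts, one per chamber. Deterministic and
#'   invariant to the ordering of replicates.
#' @examples
#' qc_classify(c(0.01, 0.009), c(0.9, 0.8), pco2_water_ppmv = 1000)
#' @export
qc_classify <- function(slopes, r2, pco2_water_ppmv, atm = atmosphere(),
                        qc = flux_constants()$qc) {
  if (length(slopes) < 1L || length(slopes) != length(r2)) {
    stop("need >= 1 fit with matching slope and r2 vectors", call. = FALSE)
  }
  replicate_mean_r2 <- mean(r2)
  uptake_ok <- pco2_water_ppmv <= (1 + qc$uptake_tol) * atm$pco2_eq_ppmv
  verdict <- character(length(slopes))
  pos <- slopes > 0
  verdict[pos & r2 > qc$r2_single] <- "retained_linear"
  verdict[pos & r2 <= qc$r2_single] <-
    if (replicate_mean_r2 >= qc$r2_replicate_mean) {
      "retained_by_replicates"
    } else {
      "discarded_nonlinear"
    }
  verdict[!pos] <- if (uptake_ok) "retained_uptake" else
    "discarded_uptake_conflict"
  verdict
}

#' Convert a chamber slope into an areal flux
#'
#' Ideal-gas conversion of the headspace accumulation rate:
#' `F = slope x 1e-6 x P / (R T) x (V/A) x 12.01 x 86400` in g C m-2 d-1,
#' with pressure in Pa, temperature in K and R = 8.314 J mol-1 K-1. Flux
#' scales linearly with the chamber's volume-to-footprint ratio, so the
#' geometry is a required input, never assumed.
#'
#' @param slope_ppm_s Fitted accumulation rate, ppm s-1.
#' @param volume_m3 Chamber headspace volume, m3.
#' @param area_m2 Chamber footprint area, m2.
#' @param air_temp_c Air temperature inside the chamber, degC.
#' @param pressure_kpa Ambient pressure, kPa.
#' @param constants Constants table.
#' @return Areal flux in g C m-2 d-1 (sign follows the slope).
#' @examples
#' slope_to_flux(0.01, volume_m3 = 0.0113, area_m2 = 0.0755,
#'               air_temp_c = 15, pressure_kpa = 101.325)
#' @export
slope_to_flux <- function(slope_ppm_s, volume_m3, area_m2, air_temp_c,
                          pressure_kpa, constants = flux_constants()) {
  if (any(!is.finite(volume_m3)) || any(!is.finite(area_m2)) ||
      any(volume_m3 <= 0) || any(area_m2 <= 0)) {
    stop("chamber geometry (volume_m3, area_m2) must be positive and finite",
         call. = FALSE)
  }
  p_pa <- pressure_kpa * 1000
  t_k <- air_temp_c + 273.15
  molar_density <- p_pa / (constants$r_gas * t_k)   # mol (of air) m-3
  slope_ppm_s * 1e-6 * molar_density * (volume_m3 / area_m2) *
    constants$molar_mass_c * 86400
}

#' Recover the CO2 gas transfer velocity from a measured chamber flux
#'
#' Inverts the diffusive flux equation: `k = F / (12.01 (c_water - c_eq))`.
#' Near air-water equilibrium the division blows up, so deployments with
#' |c_water - c_eq| below `floor_mol_m3` return `NA` (flagged, k undefined)
#' rather than a wild number.
#'
#' @param flux_gc_m2_d Measured CO2 flux, g C m-2 d-1.
#' @param pco2_water_ppmv Water pCO2, ppmv.
#' @param water_temp_c Water temperature, degC.
#' @param atm An [atmosphere()] object.
#' @param floor_mol_m3 Minimum usable concentration disequilibrium.
#' @param constants Constants table.
#' @return k for CO2 in m d-1, or `NA_real_` when the lake is too close to
#'   equilibrium to constrain k.
#' @examples
#' infer_k_from_chamber(0.5, pco2_water_ppmv = 1500, water_temp_c = 15)
#' @export
infer_k_from_chamber <- function(flux_gc_m2_d, pco2_water_ppmv, water_temp_c,
                                 atm = atmosphere(),
                                 floor_mol_m3 = flux_constants()$k_floor_mol_m3,
                                 constants = flux_constants()) {
  c_water <- gas_concentration("CO2", pco2_water_ppmv, atm$pressure_kpa,
                               water_temp_c, constants)
  c_eq <- equilibrium_concentration("CO2", atm, water_temp_c, constants)
  d <- c_water - c_eq
  k <- ifelse(abs(d) < floor_mol_m3, NA_real_,
              flux_gc_m2_d / (constants$molar_mass_c * d))
  k
}

#' Diffusive CH4 flux of one lake-season
#'
#' CH4 fluxes are concentration-based: no chamber measures CH4 directly, so
#' the transfer velocity comes either from the lake's own chamber-derived
#' CO2 velocity rescaled by `(Sc_CH4 / Sc_CO2)^n` (default), or from a
#' wind-model k600 when no usable chamber velocity exists (near-equilibrium
#' lakes). The source actually used is recorded in the result.
#'
#' @param pch4_ppmv Water pCH4, ppmv.
#' @param water_temp_c Water temperature, degC.
#' @param atm An [atmosphere()] object.
#' @param k_co2_m_d Chamber-derived CO2 transfer velocity, m d-1, or `NA`.
#' @param u10_m_s Wind speed for the fallback wind model (Cole & Caraco), or
#'   `NA` if unavailable.
#' @param exponent Schmidt exponent; default from constants.
#' @param constants Constants table.
#' @return List: `flux_gc_m2_d`, `k_ch4_m_d`, `k_source` (one of
#'   `"chamber_derived"`, `"wind_model"`).
#' @examples
#' ch4_lake_flux(20.4, 15, k_co2_m_d = 0.8)
#' @export
ch4_lake_flux <- function(pch4_ppmv, water_temp_c, atm = atmosphere(),
                          k_co2_m_d = NA_real_, u10_m_s = NA_real_,
                          exponent = NULL, constants = flux_constants()) {
  if (is.na(pch4_ppmv) || is.na(water_temp_c)) {
    stop("dissolved CH4 and water temperature are required", call. = FALSE)
  }
  if (is.null(exponent)) exponent <- constants$sc_exponent
  if (!is.na(k_co2_m_d) && k_co2_m_d > 0) {
    sc_ratio <- schmidt_number("CH4", water_temp_c, constants) /
      schmidt_number("CO2", water_temp_c, constants)
    k_ch4 <- k_co2_m_d * sc_ratio^exponent
    k_source <- "chamber_derived"
  } else if (!is.na(u10_m_s)) {
    k_ch4 <- scale_k_to_gas(k600_cole_caraco(u10_m_s), "CH4", water_temp_c,
                            exponent, constants)
    k_source <- "wind_model"
  } else {
    stop("no usable gas transfer velocity source for CH4 flux", call. = FALSE)
  }
  c_water <- gas_concentration("CH4", pch4_ppmv, atm$pressure_kpa,
                               water_temp_c, constants)
  c_eq <- equilibrium_concentration("CH4", atm, water_temp_c, constants)
  list(flux_gc_m2_d = diffusive_flux(k_ch4, c_water, c_eq, constants),
       k_ch4_m_d = k_ch4,
       k_source = k_source)
}

#' Combine one lake-season's retained chambers into a total C flux
#'
#' The lake-season CO2 flux is the unweighted arithmetic mean over retained
#' chambers (including retained uptake, which is negative), and the total C
#' flux is that mean plus the diffusive CH4 flux.
#'
#' @param flux_gc_m2_d Per-chamber CO2 fluxes, g C m-2 d-1 (`NA` for
#'   discarded chambers).
#' @param qc_verdict Per-chamber verdicts from [qc_classify()].
#' @param ch4_flux_gc_m2_d Lake-season diffusive CH4 flux, g C m-2 d-1.
#' @return List: `co2_flux_gc_m2_d`, `ch4_flux_gc_m2_d`,
#'   `total_c_flux_gc_m2_d`, `n_chambers_retained`. If no chamber survives
#'   QC all fluxes are `NA` (the lake-season is missing, not zero).
#' @examples
#' lake_season_flux(c(1, 2, 3), rep("retained_linear", 3), 0.2)
#' @export
lake_season_flux <- function(flux_gc_m2_d, qc_verdict,
                             ch4_flux_gc_m2_d = NA_real_) {
  retained <- startsWith(qc_verdict, "retained")
  n_ret <- sum(retained)
  if (n_ret == 0L) {
    return(list(co2_flux_gc_m2_d = NA_real_,
                ch4_flux_gc_m2_d = NA_real_,
                total_c_flux_gc_m2_d = NA_real_,
                n_chambers_retained = 0L))
  }
  co2 <- mean(flux_gc_m2_d[retained])
  total <- if (is.na(ch4_flux_gc_m2_d)) NA_real_ else co2 + ch4_flux_gc_m2_d
  list(co2_flux_gc_m2_d = co2,
       ch4_flux_gc_m2_d = ch4_flux_gc_m2_d,
       total_c_flux_gc_m2_d = total,
       n_chambers_retained = n_ret)
}

#' Fit and QC every chamber of a campaign
#'
#' Maps [fit_accumulation()], [qc_classify()] and [slope_to_flux()] over a
#' long-format chamber table (one row per reading), producing one row per
#' chamber deployment. Discarded chambers carry `NA` flux but keep their fit
#' diagnostics so every QC decision is auditable.
#'
#' @param chambers Data frame with columns `lake_id`, `chamber_id`, `season`,
#'   `t_s`, `co2_ppm`, `volume_m3`, `area_m2`, `air_temp_c`, `pressure_kpa`.
#' @param lakes Lake-observation table (per lake-season water state) with at
#'   least `lake_id`, `season`, `pco2_ppmv`.
#' @param atm An [atmosphere()] object.
#' @param window_h Regression window, hours.
#' @param constants Constants table (supplies QC thresholds).
#' @return Data frame of per-chamber flux estimates: identifiers, slope,
#'   intercept, `r2`, `n_points`, `window_h`, `qc_verdict`, `flux_gc_m2_d`.
#' @export
chamber_fluxes <- function(chambers, lakes, atm = atmosphere(),
                           window_h = 2.5, constants = flux_constants()) {
  require_columns(chambers, c("lake_id", "chamber_id", "season", "t_s",
                              "co2_ppm", "volume_m3", "area_m2",
                              "air_temp_c", "pressure_kpa"), "chambers")
  require_columns(lakes, c("lake_id", "season", "pco2_ppmv"), "lakes")

  key <- interaction(chambers$lake_id, chambers$season, chambers$chamber_id,
                     drop = TRUE)
  fits <- lapply(split(chambers, key), function(d) {
    d <- d[order(d$t_s), ]
    fit <- fit_accumulation(d$t_s, d$co2_ppm, window_h)
    data.frame(lake_id = d$lake_id[1], chamber_id = d$chamber_id[1],
               season = d$season[1],
               slope_ppm_s = fit$slope_ppm_s,
               intercept_ppm = fit$intercept_ppm,
               r2 = fit$r2, n_points = fit$n_points,
               window_h = fit$window_h,
               volume_m3 = d$volume_m3[1], area_m2 = d$area_m2[1],
               air_temp_c = d$air_temp_c[1],
               pressure_kpa = d$pressure_kpa[1],
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, fits)
  rownames(est) <- NULL
  est <- est[order(est$lake_id, est$season, est$chamber_id), ]

  ls_key <- interaction(est$lake_id, est$season, drop = TRUE)
  verdicts <- unsplit(lapply(split(est, ls_key), function(d) {
    pco2 <- lake_season_value(lakes, d$lake_id[1], d$season[1], "pco2_ppmv")
    qc_classify(d$slope_ppm_s, d$r2, pco2, atm, constants$qc)
  }), ls_key)
  est$qc_verdict <- verdicts
  flux <- slope_to_flux(est$slope_ppm_s, est$volume_m3, est$area_m2,
                        est$air_temp_c, est$pressure_kpa, constants)
  est$flux_gc_m2_d <- ifelse(startsWith(est$qc_verdict, "retained"),
                             flux, NA_real_)
  rownames(est) <- NULL
  est
}

#' Per-lake-season fluxes for a whole campaign
#'
#' Aggregates per-chamber estimates to one row per lake-season: mean retained
#' CO2 flux, chamber-derived CO2 transfer velocity (with wind-model fallback
#' near equilibrium), diffusive CH4 flux and total C flux.
#'
#' @param estimates Output of [chamber_fluxes()].
#' @param lakes Lake-observation table (needs `pco2_ppmv`, `pch4_ppmv`,
#'   `water_temp_c`, `zone`).
#' @param winds Optional wind table (`zone`, `season`, `u10_m_s`) used for
#'   the fallback transfer velocity.
#' @param atm An [atmosphere()] object.
#' @param constants Constants table.
#' @return Data frame, one row per lake-season, with flux components, number
#'   of retained chambers, `k_co2_m_d` and `k_source`. Lake-seasons whose
#'   chambers were all discarded appear with `NA` fluxes.
#' @export
lake_season_fluxes <- function(estimates, lakes, winds = NULL,
                               atm = atmosphere(),
                               constants = flux_constants()) {
  require_columns(lakes, c("lake_id", "season", "zone", "pco2_ppmv",
                           "pch4_ppmv", "water_temp_c", "pressure_kpa"),
                  "lakes")
  ls_key <- interaction(estimates$lake_id, estimates$season, drop = TRUE)
  rows <- lapply(split(estimates, ls_key), function(d) {
    lake_id <- d$lake_id[1]
    season <- d$season[1]
    lrow <- lakes[lakes$lake_id == lake_id & lakes$season == season, ]
    if (nrow(lrow) != 1L) {
      stop("no unique lake observation for ", lake_id, " / ", season,
           call. = FALSE)
    }
    u10 <- NA_real_
    if (!is.null(winds)) {
      w <- winds[winds$zone == lrow$zone & winds$season == season, ]
      if (nrow(w) >= 1L) u10 <- w$u10_m_s[1]
    }
    base <- lake_season_flux(d$flux_gc_m2_d, d$qc_verdict,
                             ch4_flux_gc_m2_d = NA_real_)
    k_co2 <- NA_real_
    ch4 <- list(flux_gc_m2_d = NA_real_, k_ch4_m_d = NA_real_,
                k_source = NA_character_)
    if (base$n_chambers_retained > 0L) {
      k_co2 <- infer_k_from_chamber(base$co2_flux_gc_m2_d, lrow$pco2_ppmv,
                                    lrow$water_temp_c, atm,
                                    constants$k_floor_mol_m3, constants)
      if (is.na(k_co2) || k_co2 <= 0) k_co2 <- NA_real_
      ch4 <- ch4_lake_flux(lrow$pch4_ppmv, lrow$water_temp_c, atm,
                           k_co2_m_d = k_co2, u10_m_s = u10,
                           constants = constants)
    }
    total <- if (base$n_chambers_retained > 0L)
      base$co2_flux_gc_m2_d + ch4$flux_gc_m2_d else NA_real_
    data.frame(lake_id = lake_id, season = season, zone = lrow$zone,
               co2_flux_gc_m2_d = base$co2_flux_gc_m2_d,
               ch4_flux_gc_m2_d = ch4$flux_gc_m2_d,
               total_c_flux_gc_m2_d = total,
               n_chambers_retained = base$n_chambers_retained,
               k_co2_m_d = k_co2,
               k_ch4_m_d = ch4$k_ch4_m_d,
               k_source = ch4$k_source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lake_id, out$season), ]
  rownames(out) <- NULL
  out
}

# internal helpers ----------------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

lake_season_value <- function(lakes, lake_id, season, col) {
  v <- lakes[lakes$lake_id == lake_id & lakes$season == season, col]
  if (length(v) != 1L) {
    stop("no unique ", col, " for lake ", lake_id, " season ", season,
         call. = FALSE)
  }
  v
}
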