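#' Wind-model fluxes for every lake-season
#'
#' Recomputes CO2 and diffusive CH4 fluxes from a wind-based k600 model
#' instead of chambers: k600 from the chosen parameterization, Schmidt-
#' rescaled per gas at in-situ temperature, times the concentration
#' disequilibrium against the reference atmosphere. The Vachon & Prairie
#' model additionally needs the lake area (summer extent).
#'
#' @param lakes Lake-observation table (`lake_id`, `season`, `zone`,
#'   `area_m2`, `water_temp_c`, `pco2_ppmv`, `pch4_ppmv`, `pressure_kpa`).
#' @param winds Wind table (`zone`, `season`, `u10_m_s`).
#' @param model `"cole_caraco"` or `"vachon_prairie"`.
#' @param atm An [atmosphere()] object.
#' @param constants Constants table.
#' @return Data frame, one row per lake-season: `u10_m_s`, `k600_cm_h`,
#'   `co2_flux_gc_m2_d`, `ch4_flux_gc_m2_d`, `model`.
#' @export
modelled_fluxes <- function(lakes, winds,
                            model = c("cole_caraco", "vachon_prairie"),
                            atm = atmosphere(),
                            constants = flux_constants()) {
  model <- match.arg(model)
  require_columns(lakes, c("lake_id", "season", "zone", "water_temp_c",
                           "pco2_ppmv", "pch4_ppmv"), "lakes")
  require_columns(winds, c("zone", "season", "u10_m_s"), "winds")
  if (model == "vachon_prairie" &&
      (is.null(lakes$area_m2) || any(is.na(lakes$area_m2)))) {
    stop("the vachon_prairie model requires lake area (area_m2)",
         call. = FALSE)
  }
  m <- merge(lakes, winds[, c("zone", "season", "u10_m_s")],
             by = c("zone", "season"), all.x = TRUE, sort = FALSE)
  if (any(is.na(m$u10_m_s))) {
    stop("missing wind record for some lake-seasons", call. = FALSE)
  }
  k600 <- if (model == "cole_caraco") {
    k600_cole_caraco(m$u10_m_s)
  } else {
    k600_vachon_prairie(m$u10_m_s, m$area_m2 / 1e6)
  }
  flux_for <- function(gas, ppmv) {
    k <- scale_k_to_gas(k600, gas, m$water_temp_c, constants = constants)
    cw <- gas_concentration(gas, ppmv, atm$pressure_kpa, m$water_temp_c,
                            constants)
    ce <- equilibrium_concentration(gas, atm, m$water_temp_c, constants)
    diffusive_flux(k, cw, ce, constants)
  }
  out <- data.frame(lake_id = m$lake_id, season = m$season, zone = m$zone,
                    u10_m_s = m$u10_m_s, k600_cm_h = k600,
                    co2_flux_gc_m2_d = flux_for("CO2", m$pco2_ppmv),
                    ch4_flux_gc_m2_d = flux_for("CH4", m$pch4_ppmv),
                    model = model, stringsAsFactors = FALSE)
  out <- out[order(out$lake_id, out$season), ]
  rownames(out) <- NULL
  out
}

#' Compare chamber-measured against wind-modelled fluxes
#'
#' Quantifies the disagreement per gas in two ways: (i) the ratio of means,
#' `mean(measured) / mean(modelled)` over paired lake-seasons (all pairs,
#' including uptake, so the "on average X-times lower" reading is preserved);
#' (ii) a paired log10-log10 regression restricted to pairs where both
#' fluxes are positive. With fewer than `min_pairs` positive pairs the
#' regression is flagged absent rather than fit.
#'
#' @param measured Output of [lake_season_fluxes()].
#' @param modelled Output of [modelled_fluxes()] (same campaign).
#' @param min_pairs Minimum positive pairs for the regression.
#' @return List with one element per gas (`co2`, `ch4`), each containing
#'   `mean_ratio`, `n_pairs`, and `regression` (list of `slope`,
#'   `intercept`, `r2`, `n` — or `NULL` when flagged absent).
#' @export
compare_fluxes <- function(measured, modelled, min_pairs = 3L) {
  m <- merge(measured, modelled, by = c("lake_id", "season"),
             suffixes = c("_meas", "_mod"))
  one_gas <- function(meas, mod) {
    ok <- !is.na(meas) & !is.na(mod)
    meas <- meas[ok]; mod <- mod[ok]
    if (length(meas) == 0L) stop("no paired fluxes to compare", call. = FALSE)
    ratio <- mean(meas) / mean(mod)
    pos <- meas > 0 & mod > 0
    regression <- NULL
    if (sum(pos) >= min_pairs) {
      x <- log10(mod[pos]); y <- log10(meas[pos])
      fit <- stats::lm(y ~ x)
      ss_tot <- sum((y - mean(y))^2)
      regression <- list(slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]),
                         r2 = if (ss_tot == 0) 0 else
                           1 - sum(stats::residuals(fit)^2) / ss_tot,
                         n = sum(pos))
    }
    list(mean_ratio = ratio, n_pairs = length(meas),
         regression = regression)
  }
  list(co2 = one_gas(m$co2_flux_gc_m2_d_meas, m$co2_flux_gc_m2_d_mod),
       ch4 = one_gas(m$ch4_flux_gc_m2_d_meas, m$ch4_flux_gc_m2_d_mod))
}
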