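#' Mean and interquartile range
#'
#' The survey's dispersion convention: because lake variables are strongly
#' right-skewed, uncertainty is reported as mean +/- IQR rather than a
#' standard deviation. Quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector (NAs dropped); must leave >= 1 value.
#' @return List: `mean`, `iqr` (Q75 - Q25, >= 0), `n`.
#' @examples
#' mean_iqr(c(1, 2, 3, 4))  # mean 2.5, iqr 1.5
#' @export
mean_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("mean_iqr needs >= 1 value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  list(mean = mean(values), iqr = q[2] - q[1], n = length(values))
}

#' Annual C emission of one lake
#'
#' Annualizes seasonal daily fluxes: the mean daily total C flux (unweighted
#' mean over the available seasonal campaigns) times the lake's number of
#' ice-free days, converted to kg C m-2 yr-1. The CH4 share is computed from
#' the seasonal CH4 means the same way. Net-uptake lakes keep their negative
#' annual emission; for those the CH4 share is undefined (`NA`).
#'
#' @param total_c_flux_gc_m2_d Seasonal total C fluxes, g C m-2 d-1 (up to
#'   one per campaign; NAs = missing seasons are dropped).
#' @param ch4_flux_gc_m2_d Seasonal diffusive CH4 fluxes, same length.
#' @param ice_free_days Number of ice-free days for this lake, in (0, 365).
#' @return List: `mean_daily_total_c`, `annual_c` (kg C m-2 yr-1),
#'   `annual_ch4`, `ch4_share_pct`, `n_seasons`.
#' @examples
#' annual_emission(c(2, 1, 3), c(0.2, 0.1, 0.3), 100)
#' @export
annual_emission <- function(total_c_flux_gc_m2_d, ch4_flux_gc_m2_d,
                            ice_free_days) {
  ok <- !is.na(total_c_flux_gc_m2_d)
  if (sum(ok) == 0L) {
    stop("at least one seasonal flux is required", call. = FALSE)
  }
  if (ice_free_days <= 0 || ice_free_days >= 365) {
    stop("ice_free_days must lie in (0, 365)", call. = FALSE)
  }
  mean_total <- mean(total_c_flux_gc_m2_d[ok])
  annual_c <- mean_total * ice_free_days / 1000
  ok4 <- !is.na(ch4_flux_gc_m2_d)
  annual_ch4 <- if (sum(ok4) > 0L) {
    mean(ch4_flux_gc_m2_d[ok4]) * ice_free_days / 1000
  } else {
    NA_real_
  }
  share <- if (!is.na(annual_ch4) && annual_c > 0) {
    100 * annual_ch4 / annual_c
  } else {
    NA_real_
  }
  if (!is.na(share) && (share < 0 || share > 100)) share <- NA_real_
  list(mean_daily_total_c = mean_total,
       annual_c = annual_c,
       annual_ch4 = annual_ch4,
       ch4_share_pct = share,
       n_seasons = sum(ok))
}

#' Annualize a lake-season flux table
#'
#' Applies [annual_emission()] to every lake of a [lake_season_fluxes()]
#' table, attaching zone and ice-free days from the lake-observation table.
#' Lakes with no retained season are dropped (with a message).
#'
#' @param lake_season Output of [lake_season_fluxes()].
#' @param lakes Lake-observation table with `lake_id`, `zone`,
#'   `ice_free_days`.
#' @return Data frame, one row per lake: `lake_id`, `zone`, `ice_free_days`,
#'   `mean_daily_total_c`, `annual_c`, `annual_ch4`, `ch4_share_pct`,
#'   `n_seasons`.
#' @export
annualize <- function(lake_season, lakes) {
  require_columns(lakes, c("lake_id", "zone", "ice_free_days"), "lakes")
  rows <- lapply(split(lake_season, lake_season$lake_id), function(d) {
    if (all(is.na(d$total_c_flux_gc_m2_d))) return(NULL)
    lrow <- lakes[lakes$lake_id == d$lake_id[1], ][1, ]
    ann <- annual_emission(d$total_c_flux_gc_m2_d, d$ch4_flux_gc_m2_d,
                           lrow$ice_free_days)
    data.frame(lake_id = d$lake_id[1], zone = lrow$zone,
               ice_free_days = lrow$ice_free_days,
               mean_daily_total_c = ann$mean_daily_total_c,
               annual_c = ann$annual_c,
               annual_ch4 = ann$annual_ch4,
               ch4_share_pct = ann$ch4_share_pct,
               n_seasons = ann$n_seasons,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    message(dropped, " lake(s) had no retained season and were dropped")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Per-zone summary of annual emissions
#'
#' Mean +/- IQR and n of annual C emission for each permafrost zone, plus a
#' pooled `overall` row. Output is invariant to lake ordering.
#'
#' @param annuals Output of [annualize()].
#' @param zones Valid zone labels, south to north.
#' @return Data frame with columns `zone`, `mean_annual_c`, `iqr_annual_c`,
#'   `n`.
#' @export
zone_summary <- function(annuals,
                         zones = c("isolated", "sporadic", "discontinuous",
                                   "continuous")) {
  bad <- setdiff(unique(annuals$zone), zones)
  if (length(bad) > 0L) {
    stop("unknown zone label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  groups <- c(stats::setNames(as.list(zones), zones), list(overall = zones))
  rows <- lapply(names(groups), function(g) {
    v <- annuals$annual_c[annuals$zone %in% groups[[g]]]
    if (length(v) == 0L) return(NULL)
    s <- mean_iqr(v)
    data.frame(zone = g, mean_annual_c = s$mean, iqr_annual_c = s$iqr,
               n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' CO2-equivalent flux
#'
#' Converts C-mass fluxes into a CO2-equivalent greenhouse forcing flux:
#' CO2-C is rescaled to CO2 mass (44.01/12.01) and CH4-C to CH4 mass
#' (16.04/12.01) weighted by its 100-year global warming potential
#' (default 28).
#'
#' @param co2_flux_gc CO2 flux, g C m-2 d-1.
#' @param ch4_flux_gc CH4 flux, g C m-2 d-1.
#' @param gwp100 Global warming potential of CH4 over 100 years.
#' @param constants Constants table.
#' @return Flux in g CO2-equivalents m-2 d-1.
#' @examples
#' co2_equivalent(1, 0)  # 44.01/12.01
#' co2_equivalent(0, 1)  # 28 * 16.04/12.01
#' @export
co2_equivalent <- function(co2_flux_gc, ch4_flux_gc,
                           gwp100 = flux_constants()$gwp100_ch4,
                           constants = flux_constants()) {
  co2_flux_gc * constants$molar_mass_co2 / constants$molar_mass_c +
    gwp100 * ch4_flux_gc * constants$molar_mass_ch4 / constants$molar_mass_c
}

#' Upscale mean areal emission to a regional total
#'
#' `R = region area x lake fraction x mean areal emission`, converted from kg
#' to Tg (1e-9).
#'
#' @param region_area_m2 Regional (land) area, m2.
#' @param lake_fraction Fraction of the region covered by lakes (e.g. 0.06).
#' @param mean_areal_emission_kg_m2_yr Mean lake C emission, kg C m-2 yr-1.
#' @return Total emission in Tg C yr-1.
#' @examples
#' upscale(1.3e12, 0.06, 0.154)
#' @export
upscale <- function(region_area_m2, lake_fraction,
                    mean_areal_emission_kg_m2_yr) {
  if (any(region_area_m2 <= 0) || any(lake_fraction < 0)) {
    stop("region area must be positive and lake fraction non-negative",
         call. = FALSE)
  }
  region_area_m2 * lake_fraction * mean_areal_emission_kg_m2_yr * 1e-9
}

#' Propagate relative uncertainties onto an upscaled product
#'
#' For `R = x y` with independent relative uncertainties dx/x and dy/y:
#' `dR = |R| sqrt((dx/x)^2 + (dy/y)^2)`. Symmetric in the two uncertainties
#' and homogeneous of degree 1 in R.
#'
#' @param total_tg_yr The product R, Tg C yr-1.
#' @param rel_unc_area Relative uncertainty of the lake-area term.
#' @param rel_unc_emission Relative uncertainty of the mean-emission term.
#' @return Uncertainty dR in Tg C yr-1.
#' @examples
#' propagate_uncertainty(12, 0.15, 0.15)  # ~ 2.55
#' @export
propagate_uncertainty <- function(total_tg_yr, rel_unc_area = 0.15,
                                  rel_unc_emission = 0.15) {
  if (any(rel_unc_area < 0) || any(rel_unc_emission < 0)) {
    stop("relative uncertainties must be non-negative", call. = FALSE)
  }
  abs(total_tg_yr) * sqrt(rel_unc_area^2 + rel_unc_emission^2)
}

#' Regional estimates for a set of lake-coverage scenarios
#'
#' Literature lake-coverage estimates for a region differ; this evaluates the
#' upscaling for each scenario and propagates the uncertainty, returning one
#' regional estimate per scenario sorted by total.
#'
#' @param scenarios Data frame with columns `name`, `lake_fraction`, and
#'   optionally per-scenario `region_area_m2`, `rel_unc_area`,
#'   `rel_unc_emission` (defaults below are recycled otherwise).
#' @param region_area_m2 Default regional area, m2.
#' @param mean_areal_emission_kg_m2_yr Pooled mean lake emission,
#'   kg C m-2 yr-1.
#' @param rel_unc_area,rel_unc_emission Default relative uncertainties.
#' @return Data frame: scenario name, inputs, `total_tg_yr`,
#'   `uncertainty_tg_yr`, sorted by increasing total.
#' @examples
#' scenario_table(data.frame(name = c("low", "base"),
#'                           lake_fraction = c(0.03, 0.06)),
#'                mean_areal_emission_kg_m2_yr = 0.154)
#' @export
scenario_table <- function(scenarios, region_area_m2 = 1.3e12,
                           mean_areal_emission_kg_m2_yr,
                           rel_unc_area = 0.15, rel_unc_emission = 0.15) {
  require_columns(scenarios, c("name", "lake_fraction"), "scenarios")
  if (is.null(scenarios$region_area_m2)) {
    scenarios$region_area_m2 <- region_area_m2
  }
  if (is.null(scenarios$rel_unc_area)) scenarios$rel_unc_area <- rel_unc_area
  if (is.null(scenarios$rel_unc_emission)) {
    scenarios$rel_unc_emission <- rel_unc_emission
  }
  scenarios$mean_areal_emission_kg_m2_yr <- mean_areal_emission_kg_m2_yr
  scenarios$total_tg_yr <- upscale(scenarios$region_area_m2,
                                   scenarios$lake_fraction,
                                   mean_areal_emission_kg_m2_yr)
  scenarios$uncertainty_tg_yr <- propagate_uncertainty(
    scenarios$total_tg_yr, scenarios$rel_unc_area, scenarios$rel_unc_emission)
  scenarios <- scenarios[order(scenarios$total_tg_yr), ]
  rownames(scenarios) <- NULL
  scenarios
}
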