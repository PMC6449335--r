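#' Table schemas used by the pipeline
#'
#' A small registry mapping each table kind to its required columns and
#' column types. Tables are stored as tab-delimited text with a header and a
#' `schema_version` column; audit-friendliness beats compactness for data of
#' this size.
#'
#' @return Named list of schemas; each schema has `columns` (name -> type,
#'   one of `"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @export
table_schemas <- function() {
  list(
    lakes = list(columns = c(
      lake_id = "character", zone = "character", season = "character",
      latitude = "numeric", area_m2 = "numeric", depth_m = "numeric",
      ice_free_days = "numeric", water_temp_c = "numeric",
      air_temp_c = "numeric", pressure_kpa = "numeric",
      pco2_ppmv = "numeric", pch4_ppmv = "numeric",
      ch4_dissolved_umol_l = "numeric", doc_mg_l = "numeric",
      o2_sat_pct = "numeric")),
    chambers = list(columns = c(
      lake_id = "character", chamber_id = "character", season = "character",
      t_s = "numeric", co2_ppm = "numeric", volume_m3 = "numeric",
      area_m2 = "numeric", air_temp_c = "numeric",
      pressure_kpa = "numeric")),
    winds = list(columns = c(
      zone = "character", season = "character", u10_m_s = "numeric",
      station_distance_km = "numeric")),
    chamber_fits = list(columns = c(
      lake_id = "character", chamber_id = "character", season = "character",
      slope_ppm_s = "numeric", r2 = "numeric", n_points = "integer",
      window_h = "numeric", qc_verdict = "character",
      flux_gc_m2_d = "numeric")),
    lake_season = list(columns = c(
      lake_id = "character", season = "character", zone = "character",
      co2_flux_gc_m2_d = "numeric", ch4_flux_gc_m2_d = "numeric",
      total_c_flux_gc_m2_d = "numeric", n_chambers_retained = "integer",
      k_co2_m_d = "numeric", k_source = "character")),
    annual = list(columns = c(
      lake_id = "character", zone = "character", ice_free_days = "numeric",
      mean_daily_total_c = "numeric", annual_c = "numeric",
      ch4_share_pct = "numeric", n_seasons = "integer")),
    regional = list(columns = c(
      name = "character", lake_fraction = "numeric",
      total_tg_yr = "numeric", uncertainty_tg_yr = "numeric"))
  )
}

SCHEMA_VERSION <- "1"

#' Read a validated pipeline table
#'
#' Reads a tab-delimited, headered table and validates it against the named
#' schema: missing required columns are an error naming the column; extra
#' columns produce a warning and are preserved untouched; malformed values
#' in required numeric columns are an error naming the row.
#'
#' @param path File path.
#' @param schema_name One of `names(table_schemas())`.
#' @return A data frame with typed columns.
#' @export
read_campaign_table <- function(path, schema_name) {
  schema <- table_schemas()[[schema_name]]
  if (is.null(schema)) {
    stop("unknown schema: ", schema_name, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  cols <- schema$columns
  missing <- setdiff(names(cols), names(df))
  if (length(missing) > 0L) {
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(names(cols), "schema_version"))
  if (length(extra) > 0L) {
    warning("table ", path, " has unexpected column(s), preserved: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  for (cn in names(cols)) {
    type <- cols[[cn]]
    if (type %in% c("numeric", "integer")) {
      v <- df[[cn]]
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "NA")
      if (length(bad) > 0L) {
        stop("malformed value in column ", cn, " of ", path,
             " at row ", bad[1], call. = FALSE)
      }
      df[[cn]] <- if (type == "integer") as.integer(coerced) else coerced
    } else if (type == "logical") {
      df[[cn]] <- as.logical(df[[cn]])
    } else {
      df[[cn]] <- as.character(df[[cn]])
    }
  }
  df
}

#' Write a pipeline table
#'
#' Tab-delimited text with header and a `schema_version` column. A
#' write-then-read round trip through [read_campaign_table()] is lossless
#' for the schema columns.
#'
#' @param df Data frame conforming to the schema.
#' @param path Output path.
#' @param schema_name One of `names(table_schemas())`.
#' @return `path`, invisibly.
#' @export
write_campaign_table <- function(df, path, schema_name) {
  schema <- table_schemas()[[schema_name]]
  if (is.null(schema)) stop("unknown schema: ", schema_name, call. = FALSE)
  require_columns(df, names(schema$columns), schema_name)
  df$schema_version <- SCHEMA_VERSION
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic campaign to a directory
#'
#' Emits the lakes, chambers and winds tables plus the exact configuration
#' used (YAML), so a campaign directory is self-describing and re-readable.
#'
#' @param campaign Output of [simulate_campaign()] (or a compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_campaign_table(campaign$lakes, file.path(dir, "lakes.tsv"), "lakes")
  write_campaign_table(campaign$chambers, file.path(dir, "chambers.tsv"),
                       "chambers")
  write_campaign_table(campaign$winds, file.path(dir, "winds.tsv"), "winds")
  if (!is.null(campaign$config)) {
    cfg <- campaign$config
    yaml::write_yaml(lapply(unclass(cfg), function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x))
        as.list(stats::setNames(as.vector(x), names(x))) else x),
      file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a campaign directory
#'
#' @param dir Directory written by [write_campaign()] (or hand-assembled
#'   with the same file names).
#' @return List with `lakes`, `chambers`, `winds` data frames.
#' @export
read_campaign <- function(dir) {
  list(lakes = read_campaign_table(file.path(dir, "lakes.tsv"), "lakes"),
       chambers = read_campaign_table(file.path(dir, "chambers.tsv"),
                                      "chambers"),
       winds = read_campaign_table(file.path(dir, "winds.tsv"), "winds"))
}

#' Default lake-coverage scenarios
#'
#' The base 6% coverage plus lower/higher literature-style coverages for
#' sensitivity; the pipeline evaluates all of them.
#'
#' @return Data frame with `name` and `lake_fraction`.
#' @export
default_scenarios <- function() {
  data.frame(name = c("coverage_3pct", "coverage_6pct", "coverage_9pct"),
             lake_fraction = c(0.03, 0.06, 0.09),
             stringsAsFactors = FALSE)
}

#' Run the full estimation pipeline on a campaign
#'
#' Chamber slope fits and QC -> per-chamber fluxes -> per lake-season CO2 +
#' diffusive CH4 -> per-lake annual emission -> zone summaries -> pooled
#' mean -> regional upscaling with propagated uncertainty -> wind-model
#' comparison. Deterministic: rerunning on the same campaign reproduces the
#' numbers bit for bit.
#'
#' @param campaign List with `lakes`, `chambers`, `winds` (e.g. from
#'   [simulate_campaign()] or [read_campaign()]).
#' @param atm Reference [atmosphere()].
#' @param constants Constants table.
#' @param region_area_m2 Regional area for upscaling, m2.
#' @param scenarios Lake-coverage scenario table; see [default_scenarios()].
#' @param window_h Chamber regression window, hours.
#' @return List of result tables: `chamber_fits`, `lake_season`, `annual`,
#'   `zone_summary`, `pooled` (mean/iqr/n of annual emission), `regional`,
#'   `wind_comparison` (both k600 models), and `meta` (constants version,
#'   atmosphere, window).
#' @export
run_pipeline <- function(campaign, atm = atmosphere(),
                         constants = flux_constants(),
                         region_area_m2 = 1.3e12,
                         scenarios = default_scenarios(),
                         window_h = 2.5) {
  for (nm in c("lakes", "chambers", "winds")) {
    if (is.null(campaign[[nm]])) {
      stop("pipeline stage 'input': campaign is missing the ", nm,
           " table", call. = FALSE)
    }
  }
  fits <- chamber_fluxes(campaign$chambers, campaign$lakes, atm,
                         window_h, constants)
  lake_season <- lake_season_fluxes(fits, campaign$lakes, campaign$winds,
                                    atm, constants)
  annual <- annualize(lake_season, campaign$lakes)
  zs <- zone_summary(annual)
  pooled <- mean_iqr(annual$annual_c)
  regional <- scenario_table(scenarios, region_area_m2,
                             mean_areal_emission_kg_m2_yr = pooled$mean)
  comparison <- lapply(
    stats::setNames(c("cole_caraco", "vachon_prairie"),
                    c("cole_caraco", "vachon_prairie")),
    function(mod) {
      modelled <- modelled_fluxes(campaign$lakes, campaign$winds, mod,
                                  atm, constants)
      list(modelled = modelled,
           comparison = compare_fluxes(lake_season, modelled))
    })
  list(chamber_fits = fits,
       lake_season = lake_season,
       annual = annual,
       zone_summary = zs,
       pooled = pooled,
       regional = regional,
       wind_comparison = comparison,
       meta = list(constants_version = constants$version,
                   atmosphere = unclass(atm),
                   window_h = window_h,
                   region_area_m2 = region_area_m2))
}
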