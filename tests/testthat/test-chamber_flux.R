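test_that("fit_accumulation recovers exact lines and handles degenerate series", {
  t <- seq(0, 5400, by = 300)
  fit <- fit_accumulation(t, 400 + 0.01 * t)
  expect_equal(fit$slope_ppm_s, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept_ppm, 400, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # constant series: slope 0, r2 defined as 0 (not NaN)
  flat <- fit_accumulation(t, rep(412, length(t)))
  expect_equal(flat$slope_ppm_s, 0, tolerance = 1e-12)
  expect_identical(flat$r2, 0)
  # window restriction: a 3 h record fit over 2.5 h uses 31 of 37 points
  t3 <- seq(0, 3 * 3600, by = 300)
  expect_identical(fit_accumulation(t3, 400 + 0.01 * t3, 2.5)$n_points, 31L)
  expect_identical(fit_accumulation(t3, 400 + 0.01 * t3, 1)$n_points, 13L)
  expect_error(fit_accumulation(c(0, 300), c(1, 2)), ">= 3 points")
  expect_error(fit_accumulation(t, 400 + 0.01 * t, window_h = 3), "1, 2.5")
  expect_error(fit_accumulation(c(100, 400, 700), c(1, 2, 3)), "start at 0")
})

test_that("OLS slope and r2 agree with the closed-form oracle on noisy series", {
  set.seed(101)
  for (i in 1:20) {
    t <- seq(0, sample(c(3600, 7200, 9000), 1), by = 300)
    y <- 400 + runif(1, -0.05, 0.05) * t + rnorm(length(t), 0, 5)
    fit <- fit_accumulation(t, y)
    oracle <- ols_oracle(t, y)
    expect_equal(fit$slope_ppm_s, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept_ppm, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
  }
  # noisy series with known slope stays near truth
  set.seed(5)
  t <- seq(0, 7200, by = 300)
  y <- 400 + 0.008 * t + rnorm(length(t), 0, 5)
  fit <- fit_accumulation(t, y)
  expect_lt(abs(fit$slope_ppm_s - 0.008), 0.001)
})

test_that("QC classification follows the retention rules", {
  # clearly linear positive accumulation
  expect_identical(qc_classify(c(0.01, 0.009), c(0.9, 0.8), 1000),
                   rep("retained_linear", 2))
  # low-r2 replicates rescued by the replicate-mean rule (mean 0.6 >= 0.55)
  expect_identical(qc_classify(c(0.01, 0.01), c(0.6, 0.6), 1000),
                   rep("retained_by_replicates", 2))
  # replicate mean below 0.55 discards the low-r2 fits
  v <- qc_classify(c(0.01, 0.01, 0.01), c(0.4, 0.4, 0.5), 1000)
  expect_identical(v, rep("discarded_nonlinear", 3))
  # uptake retained only near/below atmospheric equilibrium
  expect_identical(qc_classify(-0.002, 0.8, pco2_water_ppmv = 390),
                   "retained_uptake")
  expect_identical(qc_classify(-0.002, 0.8, pco2_water_ppmv = 900),
                   "discarded_uptake_conflict")
  # the default 5% tolerance: 424.4 ppmv is still "close to" equilibrium
  expect_identical(qc_classify(-0.002, 0.8, pco2_water_ppmv = 424.3),
                   "retained_uptake")
  expect_identical(qc_classify(-0.002, 0.8, pco2_water_ppmv = 425.0),
                   "discarded_uptake_conflict")
  # the (0.75, 0.76) gap routes to the stricter linear branch
  expect_identical(qc_classify(0.01, 0.755, 1000), "retained_linear")
  # permutation invariance within a replicate set
  slopes <- c(0.01, -0.001, 0.02, 0.015)
  r2 <- c(0.9, 0.3, 0.6, 0.95)
  perm <- c(3, 1, 4, 2)
  expect_identical(qc_classify(slopes, r2, 500)[perm],
                   qc_classify(slopes[perm], r2[perm], 500))
  expect_error(qc_classify(numeric(0), numeric(0), 500), ">= 1 fit")
})

test_that("slope-to-flux conversion matches the ideal-gas hand computation", {
  expect_identical(slope_to_flux(0, 0.0113, 0.0755, 15, 101.325), 0)
  # 0.01 ppm/s, V/A = 0.15 m, 101.325 kPa, 15 C
  hand <- 0.01e-6 * (101325 / (8.314 * 288.15)) * 0.15 * 12.01 * 86400
  expect_equal(slope_to_flux(0.01, 0.15 * 0.0755, 0.0755, 15, 101.325),
               hand, tolerance = 1e-12)
  expect_equal(hand, 0.0658, tolerance = 1e-3)
  # doubling V/A doubles the flux
  f1 <- slope_to_flux(0.01, 0.15 * 0.0755, 0.0755, 15, 101.325)
  f2 <- slope_to_flux(0.01, 0.30 * 0.0755, 0.0755, 15, 101.325)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_error(slope_to_flux(0.01, NA, 0.0755, 15, 101.325), "geometry")
  expect_error(slope_to_flux(0.01, 0.0113, 0, 15, 101.325), "geometry")
})

test_that("chamber-derived k inverts the flux equation and guards equilibrium", {
  atm <- atmosphere()
  # round trip: flux built from a known k recovers that k
  k_true <- 0.87
  cw <- gas_concentration("CO2", 1500, atm$pressure_kpa, 12)
  ce <- equilibrium_concentration("CO2", atm, 12)
  flux <- diffusive_flux(k_true, cw, ce)
  expect_equal(infer_k_from_chamber(flux, 1500, 12, atm), k_true,
               tolerance = 1e-12)
  # hand arithmetic: F = 0.5, c_water - c_eq = 0.05 -> k ~ 0.833
  k <- 0.5 / (12.01 * 0.05)
  expect_equal(k, 0.8326, tolerance = 1e-3)
  # near-equilibrium lakes are flagged, not divided through
  expect_true(is.na(infer_k_from_chamber(0.01, 404.2, 12, atm)))
})

test_that("lake CH4 flux uses chamber-derived k with wind-model fallback", {
  atm <- atmosphere()
  # at air-water equilibrium the flux is zero regardless of k source
  eq <- ch4_lake_flux(1.8, 15, atm, k_co2_m_d = 0.5)
  expect_equal(eq$flux_gc_m2_d, 0, tolerance = 1e-12)
  # chamber-derived route equals the hand-computed chain
  res <- ch4_lake_flux(20.4, 15, atm, k_co2_m_d = 0.8)
  sc_ratio <- schmidt_number("CH4", 15) / schmidt_number("CO2", 15)
  k_ch4 <- 0.8 * sc_ratio^(-0.5)
  dc <- gas_concentration("CH4", 20.4, atm$pressure_kpa, 15) -
    equilibrium_concentration("CH4", atm, 15)
  expect_equal(res$flux_gc_m2_d, k_ch4 * dc * 12.01, tolerance = 1e-12)
  expect_identical(res$k_source, "chamber_derived")
  # fallback to the wind model when no chamber k is usable
  res_w <- ch4_lake_flux(20.4, 15, atm, k_co2_m_d = NA, u10_m_s = 3)
  expect_identical(res_w$k_source, "wind_model")
  expect_equal(res_w$k_ch4_m_d, scale_k_to_gas(k600_cole_caraco(3), "CH4", 15),
               tolerance = 1e-12)
  expect_error(ch4_lake_flux(20.4, 15, atm), "no usable")
  expect_error(ch4_lake_flux(NA, 15, atm, k_co2_m_d = 0.5), "required")
})

test_that("lake-season averaging uses retained chambers only", {
  out <- lake_season_flux(c(1, 2, 3), rep("retained_linear", 3), 0.2)
  expect_equal(out$co2_flux_gc_m2_d, 2)
  expect_equal(out$total_c_flux_gc_m2_d, 2.2)
  expect_identical(out$n_chambers_retained, 3L)
  # single chamber
  expect_equal(lake_season_flux(1.4, "retained_linear", 0)$co2_flux_gc_m2_d,
               1.4)
  # discarded chambers are excluded from the mean
  mixed <- lake_season_flux(c(1, NA, 3),
                            c("retained_linear", "discarded_nonlinear",
                              "retained_linear"), 0.1)
  expect_equal(mixed$co2_flux_gc_m2_d, 2)
  expect_identical(mixed$n_chambers_retained, 2L)
  # no survivors: the lake-season is missing, not zero
  none <- lake_season_flux(c(NA, NA), rep("discarded_nonlinear", 2), 0.1)
  expect_true(is.na(none$co2_flux_gc_m2_d))
  expect_identical(none$n_chambers_retained, 0L)
})

test_that("end-to-end chamber recovery is exact without noise and close with it", {
  # zero noise, zero contamination: fitted slopes equal the simulated truth
  cfg0 <- tiny_config(seed = 3, chamber_noise_sd_ppm = 0,
                      contamination_rate = 0, chamber_cv = 0)
  camp0 <- simulate_campaign(cfg0)
  fits0 <- chamber_fluxes(camp0$chambers, camp0$lakes)
  m0 <- merge(fits0, camp0$truth_chambers,
              by = c("lake_id", "season", "chamber_id"))
  expect_true(all(abs(m0$slope_ppm_s - m0$true_slope_ppm_s) <
                    1e-9 * pmax(abs(m0$true_slope_ppm_s), 1e-6)))
  # within 1% of the true flux for every retained chamber
  ret0 <- !is.na(m0$flux_gc_m2_d)
  expect_true(all(abs(m0$flux_gc_m2_d[ret0] - m0$true_flux_gc_m2_d[ret0]) <=
                    0.01 * abs(m0$true_flux_gc_m2_d[ret0]) + 1e-12))
  # default logger noise: median recovered chamber flux within 5% of truth
  camp <- default_campaign()
  fits <- default_pipeline()$chamber_fits
  m <- merge(fits[startsWith(fits$qc_verdict, "retained"), ],
             camp$truth_chambers, by = c("lake_id", "season", "chamber_id"))
  rel_err <- abs(m$flux_gc_m2_d - m$true_flux_gc_m2_d) /
    abs(m$true_flux_gc_m2_d)
  expect_lt(median(rel_err), 0.05)
})
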