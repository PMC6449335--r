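test_that("mean_iqr uses linear-interpolation quantiles", {
  s <- mean_iqr(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$iqr, 1.5)  # Q75 = 3.25, Q25 = 1.75 by interpolation
  expect_identical(s$n, 4L)
  expect_equal(mean_iqr(5)$mean, 5)
  expect_equal(mean_iqr(5)$iqr, 0)
  expect_equal(mean_iqr(rep(2.2, 9))$iqr, 0)
  expect_error(mean_iqr(numeric(0)), ">= 1")
})

test_that("annual emission multiplies mean daily flux by ice-free days", {
  a <- annual_emission(c(2, 1, 3), c(0.2, 0.1, 0.3), 100)
  expect_equal(a$annual_c, 0.2)               # 2 g C m-2 d-1 * 100 d / 1000
  expect_equal(a$mean_daily_total_c, 2)
  expect_equal(a$ch4_share_pct, 10)           # 0.02 / 0.2
  expect_identical(a$n_seasons, 3L)
  # a single available season carries the year
  one <- annual_emission(c(NA, 1.5, NA), c(NA, 0.15, NA), 120)
  expect_equal(one$annual_c, 1.5 * 120 / 1000)
  expect_identical(one$n_seasons, 1L)
  # net-uptake lakes keep a negative annual emission; CH4 share is undefined
  up <- annual_emission(c(-0.5, -0.2, -0.3), c(0.01, 0.01, 0.01), 150)
  expect_lt(up$annual_c, 0)
  expect_true(is.na(up$ch4_share_pct))
  expect_error(annual_emission(c(NA, NA, NA), c(NA, NA, NA), 100),
               "at least one")
  expect_error(annual_emission(1, 0.1, 0), "ice_free_days")
})

test_that("zone summaries are exact on constants and order-invariant", {
  ann <- data.frame(
    lake_id = sprintf("L%02d", 1:6),
    zone = rep(c("isolated", "continuous"), each = 3),
    annual_c = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3))
  zs <- zone_summary(ann)
  expect_equal(zs$mean_annual_c[zs$zone == "isolated"], 0.1)
  expect_equal(zs$mean_annual_c[zs$zone == "continuous"], 0.3)
  expect_equal(zs$iqr_annual_c[zs$zone != "overall"], c(0, 0))
  expect_equal(zs$mean_annual_c[zs$zone == "overall"], 0.2)
  # permuting lakes leaves the summary unchanged
  perm <- sample(nrow(ann))
  expect_identical(zone_summary(ann[perm, ]), zs)
  expect_error(zone_summary(transform(ann, zone = "tundra")), "unknown zone")
})

test_that("CO2-equivalent conversion weights CH4 by its warming potential", {
  expect_equal(co2_equivalent(1, 0), 44.01 / 12.01, tolerance = 1e-12)
  expect_equal(co2_equivalent(0, 1), 28 * 16.04 / 12.01, tolerance = 1e-12)
  expect_equal(co2_equivalent(0, 1), 37.4, tolerance = 1e-3)
  # gwp = 1 reduces to pure mass conversion
  expect_equal(co2_equivalent(0, 1, gwp100 = 1), 16.04 / 12.01,
               tolerance = 1e-12)
})

test_that("upscaling is linear and reproduces the regional magnitude", {
  expect_equal(upscale(1.3e12, 0.06, 0.1538), 11.9964, tolerance = 1e-9)
  expect_identical(upscale(1.3e12, 0, 0.1538), 0)
  # linear in each argument
  expect_equal(upscale(2 * 1.3e12, 0.06, 0.1538),
               2 * upscale(1.3e12, 0.06, 0.1538), tolerance = 1e-12)
  expect_equal(upscale(1.3e12, 0.12, 0.1538),
               2 * upscale(1.3e12, 0.06, 0.1538), tolerance = 1e-12)
  expect_error(upscale(-1, 0.06, 0.1), "positive")
})

test_that("uncertainty propagation is the root-sum-square of relative errors", {
  expect_equal(propagate_uncertainty(12, 0.15, 0.15), 12 * sqrt(2 * 0.15^2),
               tolerance = 1e-12)
  expect_identical(propagate_uncertainty(12, 0, 0), 0)
  expect_equal(propagate_uncertainty(10, 0.3, 0.4), 5, tolerance = 1e-12)
  # symmetric in the two uncertainties, homogeneous of degree 1 in R
  set.seed(21)
  for (i in 1:10) {
    r <- runif(1, 1, 50); a <- runif(1, 0, 0.5); b <- runif(1, 0, 0.5)
    expect_equal(propagate_uncertainty(r, a, b), propagate_uncertainty(r, b, a),
                 tolerance = 1e-12)
    expect_equal(propagate_uncertainty(3 * r, a, b),
                 3 * propagate_uncertainty(r, a, b), tolerance = 1e-12)
  }
  expect_error(propagate_uncertainty(12, -0.1, 0.15), "non-negative")
})

test_that("scenario tables compose upscale and propagation, sorted by total", {
  sc <- scenario_table(data.frame(name = c("base", "low"),
                                  lake_fraction = c(0.06, 0.03)),
                       mean_areal_emission_kg_m2_yr = 0.1538)
  expect_identical(sc$name, c("low", "base"))  # sorted by total
  base <- sc[sc$name == "base", ]
  expect_equal(base$total_tg_yr, upscale(1.3e12, 0.06, 0.1538),
               tolerance = 1e-12)
  expect_equal(base$uncertainty_tg_yr,
               propagate_uncertainty(base$total_tg_yr, 0.15, 0.15),
               tolerance = 1e-12)
  # halving coverage halves the total exactly
  expect_equal(sc$total_tg_yr[sc$name == "base"],
               2 * sc$total_tg_yr[sc$name == "low"], tolerance = 1e-12)
})

test_that("unit conversions round-trip to machine precision", {
  set.seed(33)
  daily <- runif(20, -1, 5)        # g C m-2 d-1
  days <- sample(100:200, 20, replace = TRUE)
  annual <- daily * days / 1000    # kg C m-2 yr-1
  expect_equal(annual * 1000 / days, daily, tolerance = 1e-12)
  total <- upscale(1.3e12, 0.06, annual)
  expect_equal(total / (1.3e12 * 0.06 * 1e-9), annual, tolerance = 1e-12)
})

test_that("annualize aggregates a lake-season table per lake", {
  ls <- data.frame(
    lake_id = rep(c("A", "B"), each = 3),
    season = rep(c("spring", "summer", "autumn"), 2),
    zone = rep(c("isolated", "continuous"), each = 3),
    co2_flux_gc_m2_d = c(1.8, 0.9, 2.7, NA, 1, 2),
    ch4_flux_gc_m2_d = c(0.2, 0.1, 0.3, NA, 0.1, 0.2),
    total_c_flux_gc_m2_d = c(2, 1, 3, NA, 1.1, 2.2),
    n_chambers_retained = c(3L, 2L, 3L, 0L, 2L, 2L))
  lakes <- data.frame(lake_id = c("A", "B"),
                      zone = c("isolated", "continuous"),
                      ice_free_days = c(170, 150))
  ann <- annualize(ls, lakes)
  expect_equal(ann$annual_c[ann$lake_id == "A"], 2 * 170 / 1000)
  # lake B averages its two retained seasons only
  expect_equal(ann$annual_c[ann$lake_id == "B"], 1.65 * 150 / 1000)
  expect_identical(ann$n_seasons, c(3L, 2L))
})
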