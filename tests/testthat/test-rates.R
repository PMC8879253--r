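test_that("the growth-rate estimator is exact on noiseless exponentials", {
  for (mu in c(0.001, 0.017, 0.051, 0.2)) {
    tt <- seq(0, 80, length.out = 12)
    cur <- growth_curve(tt, 0.1 * exp(mu * tt))
    est <- fit_specific_growth_rate(cur)
    expect_equal(as.numeric(est), mu, tolerance = 1e-10)
  }
  # constant biomass fits a zero slope over an explicit window
  flat <- growth_curve(0:10, rep(2, 11))
  expect_equal(as.numeric(fit_specific_growth_rate(flat, c(0, 10))), 0)
})

test_that("the auto-window excludes the stationary phase", {
  spec <- curve_spec(0.051, 0.65, s0 = 5, t_end = 150, n_points = 20,
                     substrate = "glucose")
  cur <- gen_batch_curve(spec)
  est <- fit_specific_growth_rate(cur)
  expect_equal(as.numeric(est), 0.051, tolerance = 1e-6)
  expect_gte(attr(est, "r_squared"), 0.98)
})

test_that("the uptake estimator is exact on the ideal batch model", {
  spec <- curve_spec(0.023, 0.44, s0 = 12, t_end = 200, n_points = 15)
  cur <- gen_batch_curve(spec)
  qs <- fit_uptake_rate(cur, "glycerol")
  expect_equal(as.numeric(qs), 0.44, tolerance = 1e-6)
  # zero consumption gives a zero rate
  flatS <- growth_curve(cur$time, cur$biomass,
                        data.frame(glycerol = rep(5, length(cur$time))))
  expect_equal(as.numeric(fit_uptake_rate(flatS, "glycerol")), 0)
  # increasing substrate is a data error
  upS <- growth_curve(cur$time, cur$biomass,
                      data.frame(glycerol = seq(1, 5, length.out = length(cur$time))))
  expect_error(fit_uptake_rate(upS, "glycerol"), "increases")
})

test_that("carbon-accounting operations reproduce their closed forms", {
  expect_equal(c1_uptake(3.58, 6), 21.48)
  expect_equal(c1_uptake(2.42, 3), 7.26)
  expect_equal(c1_uptake(0, 5), 0)
  expect_equal(fraction_carbon_to_acetylcoa(4.76, 15.52), 61.34021,
               tolerance = 1e-6)
  expect_equal(fraction_carbon_to_acetylcoa(0, 10), 0)
  expect_equal(carbon_per_gdw_biomass(3.9, 0.051), 76.47059,
               tolerance = 1e-6)
  expect_equal(carbon_per_gdw_biomass(2, 2), 1)
  expect_equal(excess_carbon_pct(57.4, 42.6), 34.74178, tolerance = 1e-6)
  expect_equal(excess_carbon_pct(5, 5), 0)
})

test_that("metric computations commute with unit conversion", {
  qs <- 0.44
  a <- c1_uptake(convert_rate_units(qs, "gdw_to_vol"), 3)
  b <- convert_rate_units(c1_uptake(qs, 3), "gdw_to_vol")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("growth curves round-trip through CSV", {
  spec <- curve_spec(0.03, 0.5, noise_cv = 0.05, seed = 7)
  cur <- gen_batch_curve(spec)
  p <- file.path(tempdir(), "curve.csv")
  write_growth_curve(cur, p)
  back <- read_growth_curve(p)
  expect_equal(back$time, cur$time)
  expect_equal(back$biomass, cur$biomass, tolerance = 1e-6)
  expect_equal(back$substrate$glycerol, cur$substrate$glycerol,
               tolerance = 1e-6)
})
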