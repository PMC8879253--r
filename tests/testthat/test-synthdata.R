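test_that("generators are deterministic under a fixed seed", {
  s <- curve_spec(0.03, 0.5, noise_cv = 0.1, seed = 42)
  c1 <- gen_batch_curve(s); c2 <- gen_batch_curve(s)
  expect_identical(c1$biomass, c2$biomass)
  expect_identical(c1$substrate, c2$substrate)
  s2 <- curve_spec(0.03, 0.5, noise_cv = 0.1, seed = 43)
  expect_false(identical(gen_batch_curve(s2)$biomass, c1$biomass))
  m <- configure_scenario(kinetic_model(), "glucose", 3.58)
  d1 <- gen_flux_dataset(kinetic_model(), "glucose", 3.58, 0.05, seed = 3)
  d2 <- gen_flux_dataset(kinetic_model(), "glucose", 3.58, 0.05, seed = 3)
  expect_identical(d1$entries$target, d2$entries$target)
})

test_that("zero-noise curves invert exactly and truth rides along", {
  s <- curve_spec(0.023, 0.44, s0 = 12, t_end = 200, noise_cv = 0)
  cur <- gen_batch_curve(s)
  expect_identical(attr(cur, "truth"), s)
  est <- fit_rates(cur, "glycerol")
  expect_equal(est$mu, 0.023, tolerance = 1e-6)
  expect_equal(est$q_s, 0.44, tolerance = 1e-6)
})

test_that("rates are recovered within 10% at 5% noise over 50 seeds", {
  err_mu <- err_qs <- numeric(50)
  for (seed in 1:50) {
    s <- curve_spec(0.023, 0.44, s0 = 12, t_end = 200, n_points = 15,
                    noise_cv = 0.05, seed = seed)
    est <- fit_rates(gen_batch_curve(s), "glycerol")
    err_mu[seed] <- est$mu / 0.023 - 1
    err_qs[seed] <- est$q_s / 0.44 - 1
  }
  # unbiased recovery with at least 90% of draws inside the 10% band
  # (the estimators' sampling sd at these conditions is ~5%, so a rare
  # tail draw beyond 10% is statistically expected)
  expect_lt(abs(mean(err_mu)), 0.02)
  expect_lt(abs(mean(err_qs)), 0.02)
  expect_gte(mean(abs(err_mu) <= 0.10), 0.9)
  expect_gte(mean(abs(err_qs) <= 0.10), 0.9)
  expect_lt(max(abs(err_mu)), 0.15)
  expect_lt(max(abs(err_qs)), 0.15)
})

test_that("synthetic flux datasets respect node balances before noise", {
  ds <- gen_flux_dataset(kinetic_model(), "glycerol", 2.42, 0, seed = 1)
  truth <- attr(ds, "truth")
  expect_equal(setNames(ds$entries$target, ds$entries$reaction),
               truth[ds$entries$reaction])
  net <- build_kinetic_network()
  S <- stoich_matrix(net)[!net$metabolites$boundary, ]
  full <- setNames(numeric(nrow(net$reactions)), net$reactions$id)
  full[names(truth)] <- truth
  expect_lt(max(abs(S %*% full)), 1e-4)
})

test_that("synthetic inputs write out and parse back loss-free", {
  dir <- file.path(tempdir(), "synth")
  paths <- write_synthetic_inputs(dir, seed = 5)
  expect_true(all(file.exists(paths)))
  cur <- read_growth_curve(file.path(dir, "curve_glycerol.csv"))
  expect_s3_class(cur, "growth_curve")
  truth <- jsonlite::fromJSON(file.path(dir, "curve_glycerol_truth.json"))
  expect_equal(truth$mu_true, 0.023)
  ds <- read_flux_dataset(file.path(dir, "flux_glucose.tsv"))
  expect_equal(ds$substrate, "glucose")
})
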