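test_that("unit conversion matches the dry-weight assumptions", {
  expect_equal(convert_rate_units(0.65, "gdw_to_vol"), 3.575)
  expect_equal(convert_rate_units(0.44, "gdw_to_vol"), 2.42)
  expect_equal(convert_rate_units(1.41, "gdw_to_vol"), 7.755)
  expect_equal(convert_flux_set(3.58, "vol_to_gdw"), 3.58 / 5.5)
  expect_equal(convert_flux_set(0, "vol_to_gdw"), 0)
  # round trips are exact
  x <- c(a = 1.41, b = 0, c = 7.76)
  expect_identical(convert_flux_set(convert_flux_set(x, "vol_to_gdw"),
                                    "gdw_to_vol"), x)
  expect_equal(convert_rate_units(convert_rate_units(1.41, "gdw_to_vol"),
                                  "vol_to_gdw"), 1.41)
})

test_that("a flux set sampled from a feasible FBA solution validates at 1%", {
  sm <- get_stoich_model()
  g <- max_growth(sm, "glucose", 0.65, canonical = TRUE)
  kin_ids <- intersect(build_kinetic_network()$reactions$id,
                       names(g$solution$fluxes))
  fs <- g$solution$fluxes[kin_ids]
  spec <- flux_validation_spec(fs, tolerance = 0.01,
                               target_mu = g$mu_max * 0.99)
  v <- validate_flux_set(sm, spec)
  expect_true(v$feasible)
  expect_gte(v$achieved_mu, g$mu_max * 0.99 * 0.99)
})

test_that("conflicting constraints at zero tolerance are infeasible with diagnostics", {
  sm <- get_stoich_model()
  # an exactly zero band on a flux that must differ from mass balance
  fs <- c(glct = 0.65, hk = 0.60)   # glucose node cannot balance
  spec <- flux_validation_spec(fs, tolerance = 0,
                               target_mu = 0.01)
  v <- validate_flux_set(sm, spec)
  expect_false(v$feasible)
  expect_true(!is.null(v$diagnostics))
  expect_true(all(c("glct", "hk") %in% names(v$diagnostics)))
})

test_that("feasibility is monotone in the tolerance band", {
  sm <- get_stoich_model()
  ds <- packaged_dataset("ethanol")
  fs <- setNames(ds$entries$target, ds$entries$reaction)
  feas <- vapply(c(0.005, 0.01, 0.03, 0.08, 0.15, 0.30), function(tol) {
    sp <- scenario_validation_spec(fs, "ethanol", 0.046,
                                   tolerance = tol, relax_ppp = TRUE)
    validate_flux_set(sm, sp)$feasible
  }, logical(1))
  # once feasible, feasible at every larger tolerance
  expect_true(all(diff(as.integer(feas)) >= 0))
  expect_true(any(feas))
})

test_that("validation specs round-trip through JSON", {
  spec <- flux_validation_spec(c(glct = 0.65, acl = 0.70), 0.04,
                               relax_ppp = TRUE,
                               zeroed_exchanges = c("glyct", "etoht"),
                               target_mu = 0.051)
  p <- file.path(tempdir(), "spec.json")
  write_validation_spec(spec, p)
  back <- read_validation_spec(p)
  expect_equal(back$flux_set, spec$flux_set)
  expect_equal(back$tolerance, spec$tolerance)
  expect_equal(back$relax_ppp, spec$relax_ppp)
  expect_equal(back$zeroed_exchanges, spec$zeroed_exchanges)
  expect_equal(back$target_mu, spec$target_mu)
})
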