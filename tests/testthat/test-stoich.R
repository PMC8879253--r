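test_that("the biomass equation accounts for ~1 g of dry mass", {
  comp <- gen_biomass_composition()
  mass <- sum(comp$precursors * comp$masses[names(comp$precursors)])
  expect_gt(mass, 950); expect_lt(mass, 1050)
  expect_gte(sum(comp$fractions), 0.95)
  expect_lte(sum(comp$fractions), 1.0)
  # the DHA share of dry mass follows the composition
  expect_equal(comp$precursors[["dha_c"]] * 328.5 / 1000, 0.035,
               tolerance = 1e-6)
})

test_that("the model grows on each substrate alone and not with closed uptakes", {
  sm <- get_stoich_model()
  for (s in c("glucose", "glycerol", "ethanol", "acetate")) {
    g <- max_growth(sm, s, 1)
    expect_gt(g$mu_max, 0)
  }
  fb <- lapply(sm$substrate_exchange, function(e) c(0, 0))
  names(fb) <- unname(sm$substrate_exchange)
  closed <- solve_fba(sm, sm$biomass_reaction, fixed_bounds = fb)
  expect_lt(abs(closed$objective_value), 1e-9)
})

test_that("optimal FBA solutions balance mass, bounds and carbon", {
  sm <- get_stoich_model()
  S <- stoich_matrix(sm$network, internal_only = TRUE)
  rxn <- sm$network$reactions
  nC <- setNames(sm$network$metabolites$n_carbon, sm$network$metabolites$id)
  for (s in c("glucose", "ethanol")) {
    g <- max_growth(sm, s, 0.65, canonical = TRUE)
    v <- g$solution$fluxes
    expect_lt(max(abs(S %*% v)), 1e-9 * max(1, max(abs(v))))
    # model bounds hold for all internal reactions (exchange bounds are
    # overridden by the growth setup)
    internal <- !grepl("^ex_", rxn$id)
    expect_true(all(v[internal] >= rxn$lb[internal] - 1e-8 &
                    v[internal] <= rxn$ub[internal] + 1e-8))
    expect_true(all(abs(v) <= 1000 + 1e-8))
    # substrate carbon = biomass carbon + DHA carbon + net CO2 out
    cin <- carbon_count(s) * -v[[sm$substrate_exchange[[s]]]]
    biomass_c <- sum(sm$composition$precursors *
                     nC[names(sm$composition$precursors)]) * g$mu_max
    cout <- biomass_c + 22 * v[["ex_dha"]] + v[["ex_co2"]]
    expect_equal(cout, cin, tolerance = 1e-6 * cin)
  }
})

test_that("carbon-per-biomass is invariant to the uptake scale", {
  sm <- get_stoich_model()
  y1 <- min_carbon_per_biomass(sm, "glucose", 0.65)
  y2 <- min_carbon_per_biomass(sm, "glucose", 1.30)
  expect_equal(y1, y2, tolerance = 1e-6)
})

test_that("DHA potential rises strictly as biomass production drops", {
  sm <- get_stoich_model()
  for (s in c("glucose", "glycerol", "ethanol")) {
    u <- c(glucose = 0.65, glycerol = 0.44, ethanol = 1.41)[[s]]
    sc <- dha_potential_scan(sm, s, u)
    expect_equal(sc$status, rep("optimal", 3))
    expect_true(all(diff(sc$pct_carbon_to_dha) > 0))   # 1.0 -> 0.8 -> 0.4
    expect_true(all(diff(sc$dha_flux) > 0))
    expect_true(all(sc$pct_carbon_to_dha <= 100))
    expect_true(all(sc$dha_flux >= 0))
  }
})

test_that("a toy composition change leaves the model solvable", {
  comp <- gen_biomass_composition(c(protein = 0.2, carbohydrate = 0.4))
  sm2 <- build_stoich_model(comp)
  g <- max_growth(sm2, "glucose", 0.65)
  expect_gt(g$mu_max, 0)
  expect_error(gen_biomass_composition(c(unicorn = 0.1)), "unknown")
})

test_that("growth diagnostics identify blocked precursors", {
  sm <- get_stoich_model()
  # closing the nitrogen source must block every aminated precursor
  fb <- .growth_bounds(sm, "glucose", 0.65)
  fb[["ex_nh3"]] <- c(0, 0)
  sol <- solve_fba(sm, sm$biomass_reaction, fixed_bounds = fb)
  expect_lt(abs(sol$objective_value), 1e-9)
  blocked <- dhaflux:::.blocked_precursors(sm, fb)
  expect_true(all(c("glu_c", "asp_c", "ala_c") %in% blocked))
})
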