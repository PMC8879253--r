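test_that("rate-law forms evaluate to their closed-form values", {
  # irreversible MM at S = Km runs at half its maximal rate
  law <- rate_law("irreversible_mm", Vm = 2, Km = c(S = 0.5))
  expect_equal(evaluate_rate(law, c(S = 0.5)), 1.0)
  # reversible MM with Haldane vanishes at equilibrium (Gamma = Keq)
  rev <- rate_law("reversible_mm_haldane", Vm = 7, Km = c(S = 0.5, P = 0.5),
                  Keq = 4, substrates = c(S = 1), products = c(P = 1))
  expect_equal(evaluate_rate(rev, c(S = 1, P = 4)), 0)
  expect_gt(evaluate_rate(rev, c(S = 1, P = 1)), 0)
  expect_lt(evaluate_rate(rev, c(S = 1, P = 8)), 0)
  # a zero overexpression coefficient silences any form
  for (f in c("constant_flux", "irreversible_mm", "mass_action")) {
    z <- rate_law(f, Vm = 3, k_over = 0, Km = c(S = 0.5))
    expect_equal(evaluate_rate(z, c(S = 1)), 0)
  }
  # mass action multiplies concentrations
  ma <- rate_law("mass_action", Vm = 2, substrates = c(A = 1, B = 2))
  expect_equal(evaluate_rate(ma, c(A = 3, B = 2)), 2 * 3 * 4)
  expect_error(evaluate_rate(law, c(S = -1)), "negative")
})

test_that("a single pool with constant inflow and first-order outflow hits v/k", {
  cmp <- data.frame(id = c("e", "c"), name = c("ext", "cyt"),
                    relative_volume = c(1, 1))
  met <- data.frame(id = c("src_e", "A_c"), name = c("src", "A"),
                    compartment = c("e", "c"), formula = NA,
                    n_carbon = 1L, boundary = c(TRUE, FALSE))
  rxn <- data.frame(id = c("inflow", "outflow"), name = c("in", "out"),
                    reversible = FALSE, lb = 0, ub = 100,
                    transport = c(TRUE, FALSE), ec = NA)
  net <- metabolic_network(cmp, met, rxn,
                           list(inflow = c(src_e = -1, A_c = 1),
                                outflow = c(A_c = -1)))
  laws <- list(inflow = rate_law("constant_flux", Vm = 2),
               outflow = rate_law("mass_action", Vm = 0.5,
                                  substrates = c(A_c = 1)))
  m <- kinetic_model(net, laws)
  tr <- simulate_kinetic(m, c(A_c = 0), t_end = 40, n_points = 50)
  # analytic solution: C(t) = v/k (1 - e^(-kt)) -> 4
  expect_equal(unname(tr$concentrations[50, "A_c"]),
               4 * (1 - exp(-0.5 * 40)), tolerance = 1e-6)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_equal(unname(ss$concentrations["A_c"]), 4, tolerance = 1e-6)
})

test_that("zero uptake drains the network to the all-zero steady state", {
  m <- configure_scenario(kinetic_model(), "glucose", 0)
  ss <- find_steady_state(m, quiet = TRUE)
  expect_true(ss$converged)
  expect_true(all(abs(ss$fluxes) < 1e-6))
})

test_that("configure_scenario routes uptake and selects the PDH capacity", {
  m <- configure_scenario(kinetic_model(), "glycerol", 2.42)
  expect_equal(m$rate_laws$glyct$Vm, 2.42)
  expect_equal(m$rate_laws$glct$Vm, 0)
  expect_equal(m$rate_laws$etoht$Vm, 0)
  expect_equal(m$rate_laws$pdh$Vm, 907)
  m2 <- configure_scenario(m, "ethanol", 7.76)
  expect_equal(m2$rate_laws$pdh$Vm, 1e-6)
  expect_error(configure_scenario(m, "starch", 1))
})

test_that("steady states balance mass and carbon on every substrate", {
  for (sc in list(c("glucose", 3.58), c("glycerol", 2.42),
                  c("ethanol", 7.76))) {
    m <- configure_scenario(kinetic_model(), sc[1], as.numeric(sc[2]))
    ss <- find_steady_state(m, tol = 1e-8, quiet = TRUE)
    expect_true(ss$converged)
    # flux balance on the internal species (volume-scaled)
    net <- m$network
    S <- stoich_matrix(net)[!net$metabolites$boundary, ]
    expect_lt(max(abs(S %*% ss$fluxes)), 10 * 1e-8 * 100)
    # carbon throughput: n_C x uptake leaves via CO2 + the acetyl sink
    v <- ss$fluxes
    co2 <- v[["pdh"]] + v[["ide"]] + v[["ogdh"]] + v[["me"]] - v[["pyc"]]
    u <- as.numeric(sc[2]) * carbon_count(sc[1])
    expect_equal(co2 + 2 * v[["accoa_sink"]], u, tolerance = 1e-6 * u)
  }
})

test_that("steady-state fluxes are robust to initial-condition scaling", {
  m <- configure_scenario(kinetic_model(), "glucose", 3.58)
  base <- find_steady_state(m, quiet = TRUE)
  for (f in c(10, 0.1)) {
    init <- rep(0.1 * f, 29)
    names(init) <- names(base$concentrations)[
      !names(base$concentrations) %in%
        c("glucose_e", "glycerol_e", "ethanol_e", "accoa_sink_e",
          "coa_c", "coa_m", "co2_m")]
    ss <- find_steady_state(m, init, quiet = TRUE)
    expect_true(ss$converged)
    expect_equal(ss$fluxes, base$fluxes, tolerance = 1e-4)
  }
})

test_that("trajectories stay non-negative and approach constant fluxes", {
  m <- configure_scenario(kinetic_model(), "glucose", 3.58)
  tr <- simulate_kinetic(m, t_end = 3000, n_points = 61)
  expect_true(all(tr$concentrations >= 0))
  late <- tr$fluxes[c(60, 61), ]
  expect_lt(max(abs(late[2, ] - late[1, ])), 1e-4)
})
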