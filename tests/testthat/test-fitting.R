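test_that("the objective is zero at a perfect match and penalises caps", {
  m <- configure_scenario(kinetic_model(), "glucose", 3.58)
  ss <- find_steady_state(m, tol = 1e-8, quiet = TRUE)
  v <- ss$fluxes[abs(ss$fluxes) > 1e-6]
  ds <- flux_dataset("self", data.frame(reaction = names(v),
                                        target = unname(v), weight = 1),
                     "glucose", 3.58)
  obj <- objective_sse(m, ds)
  expect_lt(as.numeric(obj), 1e-8)
  # a simulated flux off by exactly its target (relative error 1,
  # weight 1) contributes 1.0
  ds2 <- ds
  i <- which(ds2$entries$reaction == "acl")
  ds2$entries$target[i] <- ds2$entries$target[i] / 2
  expect_equal(as.numeric(objective_sse(m, ds2)), 1.0, tolerance = 1e-6)
  # entry order does not matter
  ds3 <- ds2
  ds3$entries <- ds3$entries[rev(seq_len(nrow(ds3$entries))), ]
  expect_equal(as.numeric(objective_sse(m, ds3)),
               as.numeric(objective_sse(m, ds2)), tolerance = 1e-12)
})

test_that("concentration caps single out the right species", {
  m <- configure_scenario(kinetic_model(), "glucose", 3.58)
  ss <- find_steady_state(m, quiet = TRUE)
  expect_equal(nrow(check_constraints(ss)), 0L)
  ss2 <- ss
  ss2$concentrations["cit_c"] <- 12.5
  v <- check_constraints(ss2)
  expect_equal(v$metabolite, "cit_c")
  expect_equal(v$cap, 12)
  # cellular ethanol is allowed up to 32
  ss3 <- ss
  ss3$concentrations["ethanol_c"] <- 30
  expect_equal(nrow(check_constraints(ss3)), 0L)
  ss3$concentrations["ethanol_c"] <- 33
  expect_equal(check_constraints(ss3)$cap, 32)
})

test_that("fitting is reproducible under a fixed seed", {
  ds <- gen_flux_dataset(kinetic_model(), "glycerol", 2.42, 0, seed = 1)
  cfg <- estimation_config(seed = 11, de_pop = 5, de_gens = 3,
                           local_maxit = 3)
  f1 <- fit_parameters(kinetic_model(), ds, cfg)
  f2 <- fit_parameters(kinetic_model(), ds, cfg)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$objective, f2$objective)
})

test_that("noise-free synthetic fluxes are recovered within 2%", {
  rec <- get_recovery_fit()
  v <- rec$fit$steady_states[[1]]$fluxes[names(rec$truth)]
  rel <- abs(v - rec$truth) / pmax(abs(rec$truth), 1e-6)
  expect_lt(max(rel), 0.02)
})

test_that("the joint and ethanol fits reproduce the packaged anchors", {
  joint <- get_joint_fit()
  expect_lt(joint$objective, 5)
  expect_equal(length(joint$constraint_violations), 0L)
  vg <- joint$steady_states[["glucose_13c"]]$fluxes
  expect_equal(unname(vg["glct"]), 3.575, tolerance = 1e-6)
  # glycerol shares the parameter set and lands near its anchor
  vy <- joint$steady_states[["glycerol_batch"]]$fluxes
  expect_equal(unname(vy["acl"]), 1.44, tolerance = 0.10)
  eth <- get_ethanol_fit()
  ve <- eth$steady_states[["ethanol_batch"]]$fluxes
  expect_equal(unname(ve["acl"]), 4.76, tolerance = 0.10)
})
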