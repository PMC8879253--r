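test_that("the kinetic network has the fixed reconstruction dimensions", {
  net <- build_kinetic_network()
  expect_equal(nrow(net$reactions), 35L)
  expect_equal(nrow(net$metabolites), 36L)
  expect_equal(nrow(net$compartments), 3L)
  # no pentose phosphate pathway, no glutamate dehydrogenase, no
  # energy/redox cofactors at this scale
  expect_length(intersect(c("g6pd", "gnd", "rpi", "rpe", "tkt1", "tkt2",
                            "tal", "gdh", "oxphos", "thd", "atpdrain"),
                          net$reactions$id), 0L)
  expect_false(any(grepl("atp|nadh|nadph", names(unlist(net$stoichiometry)))))
  # PDH and PYC both consume mitochondrial pyruvate
  expect_lt(net$stoichiometry[["pdh"]][["pyr_m"]], 0)
  expect_lt(net$stoichiometry[["pyc"]][["pyr_m"]], 0)
  # mitochondria at 1% of the cytosol volume
  vols <- setNames(net$compartments$relative_volume, net$compartments$id)
  expect_equal(unname(vols["m"] / vols["c"]), 0.01)
})

test_that("every transport reaction links exactly two compartments", {
  net <- build_kinetic_network()
  comp <- setNames(net$metabolites$compartment, net$metabolites$id)
  for (id in net$reactions$id[net$reactions$transport]) {
    touched <- unique(comp[names(net$stoichiometry[[id]])])
    expect_length(touched, 2L)
  }
})

test_that("carbon is conserved in every reaction of both networks", {
  expect_identical(validate_network(build_kinetic_network(),
                                    check_elements = TRUE), character(0))
  expect_identical(validate_network(get_stoich_model()$network,
                                    check_elements = TRUE), character(0))
})

test_that("the kinetic network is a reaction-id subgraph of the stoich network", {
  kin <- build_kinetic_network()
  sm <- get_stoich_model()
  expect_true(all(kin$reactions$id %in% sm$network$reactions$id))
  expect_gte(sum(sm$network$reactions$transport), 35L)
})

test_that("carbon_count resolves substrates and network metabolites", {
  expect_equal(carbon_count("glucose"), 6L)
  expect_equal(carbon_count("glycerol"), 3L)
  expect_equal(carbon_count("ethanol"), 2L)
  expect_equal(carbon_count("acetate"), 2L)
  expect_equal(carbon_count("water"), 0L)
  net <- build_kinetic_network()
  expect_equal(carbon_count("cit_m", net), 6L)
  expect_error(carbon_count("unobtainium"), "unknown")
})

test_that("validate_network reports violations as data", {
  net <- build_kinetic_network()
  net$stoichiometry[["hk"]] <- c(glucose_c = -1, phantom_met = 1)
  v <- validate_network(net)
  expect_true(any(grepl("phantom_met", v)))
  # a 2A -> B reaction with both species at 1 carbon breaks conservation
  cmp <- data.frame(id = "c", name = "cytosol", relative_volume = 1)
  met <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
                    formula = NA, n_carbon = 1L, boundary = FALSE)
  rxn <- data.frame(id = "bad", name = "bad", reversible = FALSE,
                    lb = 0, ub = 10, transport = FALSE, ec = NA)
  bad <- metabolic_network(cmp, met, rxn, list(bad = c(A = -2, B = 1)))
  expect_true(any(grepl("conserve carbon", validate_network(bad, TRUE))))
})

test_that("equation strings and tabular files round-trip a network", {
  p <- parse_equation("2 A + 1 B -> 1 C")
  expect_equal(p$stoichiometry, c(A = -2, B = -1, C = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("A <=> B")$reversible)
  eq <- format_equation(c(A = -2, B = -1, C = 1))
  expect_equal(parse_equation(eq)$stoichiometry, c(A = -2, B = -1, C = 1))

  net <- build_kinetic_network()
  stem <- file.path(tempdir(), "kinnet")
  write_network_tsv(net, stem)
  back <- read_network_tsv(stem)
  expect_equal(back$reactions$id, net$reactions$id)
  expect_equal(back$metabolites$n_carbon, net$metabolites$n_carbon)
  for (id in net$reactions$id)
    expect_equal(sort(back$stoichiometry[[id]]),
                 sort(net$stoichiometry[[id]]))
})
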