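test_that("SBML export/import round-trips the network and rate laws", {
  net <- build_kinetic_network()
  laws <- default_rate_laws(net)
  path <- file.path(tempdir(), "kinetic.xml")
  write_sbml(net, path, rate_laws = laws)
  back <- read_sbml(path)
  expect_equal(back$network$reactions$id, net$reactions$id)
  expect_equal(back$network$metabolites$id, net$metabolites$id)
  expect_equal(back$network$metabolites$boundary, net$metabolites$boundary)
  expect_equal(back$network$compartments$relative_volume,
               net$compartments$relative_volume)
  for (id in net$reactions$id) {
    expect_equal(sort(back$network$stoichiometry[[id]]),
                 sort(net$stoichiometry[[id]]), tolerance = 1e-12)
    expect_equal(back$rate_laws[[id]]$form, laws[[id]]$form)
    expect_equal(back$rate_laws[[id]]$Vm, laws[[id]]$Vm)
  }
  # the reimported model simulates identically
  m1 <- configure_scenario(kinetic_model(), "glucose", 1)
  m2 <- configure_scenario(
    kinetic_model(back$network, back$rate_laws), "glucose", 1)
  s1 <- find_steady_state(m1, quiet = TRUE)
  s2 <- find_steady_state(m2, quiet = TRUE)
  expect_equal(s2$fluxes, s1$fluxes, tolerance = 1e-8)
})
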