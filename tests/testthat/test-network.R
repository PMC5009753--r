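test_that("the Model 1 plasmid network carries the named pathway steps", {
  net <- fx_network()
  steps <- network_steps(net)
  uni_steps <- c("s1", "s2", "s3", "s4", "r1", "r2", "mod", "modr")
  expect_true(all(uni_steps %in% steps$step))
  expect_equal(sum(steps$step %in% uni_steps), length(uni_steps))
  # binding step families b1..b4 all present
  for (b in c("b1", "b2", "b3", "b4")) {
    expect_gt(sum(startsWith(steps$step, paste0(b, ":"))), 0)
  }
  # s2/s4 are written in the desynapsis direction
  expect_equal(steps$reactants[steps$step == "s2"], "LR_int_s2")
  expect_equal(steps$products[steps$step == "s2"], "LR_int")
  expect_equal(steps$reactants[steps$step == "s4"], "PB_intrdf_s2")
})

test_that("Model 0 differs from Model 1 only by the stable product synapses", {
  sp1 <- fx_network("MODEL1_PLASMID")$species$name
  sp0 <- fx_network("MODEL0_PLASMID")$species$name
  expect_setequal(setdiff(sp1, sp0), c("LR_int_s2", "PB_intrdf_s2"))
  expect_length(setdiff(sp0, sp1), 0)
  st0 <- network_steps(fx_network("MODEL0_PLASMID"))$step
  expect_false(any(c("mod", "modr") %in% st0))
})

test_that("stoichiometry encodes exactly the expected conservation laws", {
  # plasmid: DNA, integrase and RDF totals -> rank = n_species - 3
  net <- fx_network()
  expect_equal(qr(net$stoich)$rank, nrow(net$species) - 3)
  expect_equal(max(abs(net$conservation %*% net$stoich)), 0)

  # linear fragments: attP/attB equivalents, integrase, L/R balance -> 4 laws
  netl <- fx_network("MODEL1_LINEAR")
  expect_equal(nrow(netl$conservation), 4)
  expect_equal(qr(netl$stoich)$rank, nrow(netl$species) - 4)
  expect_equal(max(abs(netl$conservation %*% netl$stoich)), 0)
})

test_that("rhs is pure mass action with conserved totals", {
  net <- fx_network()
  zero <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  expect_equal(unname(rhs(zero, net)), unname(zero))

  y0 <- initial_state(net, "pPB", 10, 400, 0)
  d <- rhs(y0, net)
  expect_equal(max(abs(net$conservation %*% d)), 0, tolerance = 1e-12)

  # at the independently derived equilibrium the derivative vanishes
  orc <- oracle_equilibrium_noRDF(fx_params(), 10, 400)
  y <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  y[names(orc$state)] <- orc$state
  expect_lt(max(abs(rhs(y, net))), 1e-10)

  expect_error(rhs(y0[-1], net), "every network species")
})

test_that("initial states place protein as free monomer and DNA unbound", {
  net <- fx_network()
  y <- initial_state(net, "pPB", 10, 400, 0)
  expect_equal(y[["PB"]], 10)
  expect_equal(y[["int"]], 400)
  expect_equal(sum(y), 410)

  y2 <- initial_state(net, "pLR", 10, 400, 800)
  expect_equal(y2[["LR"]], 10)
  expect_equal(y2[["rdf"]], 800)
  expect_equal(sum(y2), 1210)

  expect_error(initial_state(net, "pPB", -1, 400, 0), "non-negative")
  expect_error(initial_state(net, "attB", 10, 400, 0), "not available")

  # zero DNA: downstream readout is undefined and flagged
  y3 <- initial_state(net, "pPB", 0, 400, 0)
  sim <- simulate_network(net, y3, times = c(60, 120))
  expect_error(fraction_recombinant(sim), "zero total DNA")
})

test_that("conservation totals drift below 1e-6 along trajectories", {
  net <- fx_network()
  for (arm in list(c("pPB", 0), c("pLR", 800))) {
    y0 <- initial_state(net, arm[1], 10, 400, as.numeric(arm[2]))
    sim <- simulate_network(net, y0, times = c(60, 1800, 10800))
    tot0 <- conservation_totals(y0, net)
    for (i in seq_along(sim$times)) {
      tot <- conservation_totals(sim$conc[i, ], net)
      expect_lt(max(abs(tot - tot0) / pmax(tot0, 1)), 1e-6)
    }
  }
})
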