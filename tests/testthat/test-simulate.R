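test_that("no catalyst means no recombination, and none at t = 0", {
  net <- fx_network()
  y0 <- initial_state(net, "pPB", 10, 0, 0)
  sim <- simulate_network(net, y0, times = c(0, 600, 10800))
  expect_equal(unname(fraction_recombinant(sim)), c(0, 0, 0))

  y1 <- initial_state(net, "pPB", 10, 400, 0)
  sim1 <- simulate_network(net, y1, times = c(0, 60))
  expect_equal(fraction_recombinant(sim1)[1], 0)
  expect_error(simulate_network(net, y1, times = c(60, 30)),
               "strictly increasing")
})

test_that("the four reaction arms reproduce the directionality ordering", {
  p <- fx_params()
  t3 <- 3 * 3600
  expect_gt(frac_at(p, "pPB", 400, 0, t3), 0.5)      # P x B (-RDF): permitted
  expect_lt(frac_at(p, "pLR", 400, 0, t3), 0.01)     # L x R (-RDF): blocked
  expect_gt(frac_at(p, "pLR", 400, 800, t3), 0.5)    # L x R (+RDF): permitted
  expect_lt(frac_at(p, "pPB", 400, 800, t3), 0.15)   # P x B (+RDF): inhibited
})

test_that("long-time ODE composition matches the algebraic oracle", {
  net <- fx_network()
  y0 <- initial_state(net, "pPB", 10, 400, 0)
  sim <- simulate_network(net, y0, times = 10^(2:9), method = "bdf")
  yend <- sim$conc[nrow(sim$conc), ]
  orc <- oracle_equilibrium_noRDF(fx_params(), 10, 400)
  for (nm in names(orc$state)) {
    expect_equal(yend[[nm]], orc$state[[nm]],
                 tolerance = 1e-6, label = paste("ODE limit", nm))
  }
  # species absent from the -RDF oracle (RDF-containing) stayed at zero
  expect_equal(max(yend[setdiff(names(yend), names(orc$state))]), 0)
})

test_that("equilibrium is detailed-balanced and path-independent", {
  net <- fx_network()
  eqA <- eq_of(fx_params(), "pPB", 400, 0)
  eqB <- eq_of(fx_params(), "pLR", 400, 0)
  # per-step net fluxes vanish at the polished state
  expect_lt(eqA$max_step_flux, 1e-12)
  expect_lt(eqB$max_step_flux, 1e-12)
  # same totals -> same equilibrium, regardless of starting substrate
  for (nm in names(eqA$state)) {
    denom <- max(eqA$state[[nm]], 1e-9)
    expect_lt(abs(eqA$state[[nm]] - eqB$state[[nm]]) / denom, 1e-6)
  }
  # fractions are complementary views of one composition
  expect_equal(eqA$fraction_recombinant, 1 - eqB$fraction_recombinant,
               tolerance = 1e-9)
  # and agree with the independent oracle
  orc <- oracle_equilibrium_noRDF(fx_params(), 10, 400)
  expect_equal(eqA$fraction_recombinant, orc$fraction_LR, tolerance = 1e-6)
})

test_that("headline readouts are robust to 10x tighter solver tolerances", {
  net <- fx_network()
  y0 <- initial_state(net, "pPB", 10, 400, 0)
  f1 <- fraction_recombinant(simulate_network(net, y0, times = 1800))
  f2 <- fraction_recombinant(simulate_network(net, y0, times = 1800,
                                              rtol = 1e-9, atol = 1e-13))
  expect_lt(abs(f1 - f2), 0.001)
})

test_that("Model 0 equilibrates from both directions in 3 h; Model 1 does not", {
  p0 <- fx_params("MODEL0_PLASMID")
  p1 <- fx_params("MODEL1_PLASMID")
  t3 <- 3 * 3600
  # pLR fraction after 3 h, starting from either substrate (no RDF)
  m0_from_pPB <- frac_at(p0, "pPB", 400, 0, t3)
  m0_from_pLR <- 1 - frac_at(p0, "pLR", 400, 0, t3)
  m1_from_pPB <- frac_at(p1, "pPB", 400, 0, t3)
  m1_from_pLR <- 1 - frac_at(p1, "pLR", 400, 0, t3)
  expect_lt(abs(m0_from_pPB - m0_from_pLR), 0.02)
  expect_gt(abs(m1_from_pPB - m1_from_pLR), 0.2)
})
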