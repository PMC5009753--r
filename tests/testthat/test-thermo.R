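test_that("Wegscheider residuals are exact log-sum arithmetic", {
  p <- fx_params()
  # identity constants close trivially
  K1 <- p$K; K1[] <- 1
  kf1 <- p$kf; kf1[] <- 1
  p_unit <- rec_params("MODEL1_PLASMID", K1, kf1)
  expect_equal(unname(wegscheider_residuals(p_unit)), c(0, 0))

  # shipped reference sets are closed to 1e-9 in log space
  for (v in c("MODEL0_PLASMID", "MODEL1_PLASMID", "MODEL1_LINEAR")) {
    expect_lt(max(wegscheider_residuals(fx_params(v))), 1e-9)
  }

  # doubling K_r1 alone shifts the -RDF residual by exactly ln 2
  p2 <- set_constants(p, K_r1 = p$K[["K_r1"]] * 2)
  expect_equal(wegscheider_residuals(p2)[["noRDF"]], log(2), tolerance = 1e-12)
  expect_equal(wegscheider_residuals(p2)[["RDF"]], 0, tolerance = 1e-12)
})

test_that("closure recomputes the derived constants and is idempotent", {
  p <- fx_params()
  p_off <- set_constants(p, K_s2 = 1, K_s4 = 1)
  p_cl <- close_parameters(p_off)
  expect_equal(unname(wegscheider_residuals(p_cl)), c(0, 0), tolerance = 1e-12)
  expect_equal(p_cl$K[["K_s2"]], p$K[["K_s2"]], tolerance = 1e-12)
  expect_equal(close_parameters(p_cl)$K, p_cl$K, tolerance = 1e-15)

  # with K_s2 in the desynapsis direction, closure gives K_s2 ~ 1/K_r1:
  # doubling K_r1 halves the derived K_s2
  p_r <- close_parameters(set_constants(p, K_r1 = p$K[["K_r1"]] * 2))
  expect_equal(p_r$K[["K_s2"]], p$K[["K_s2"]] / 2, tolerance = 1e-12)
})

test_that("compensated perturbations preserve closure and invert cleanly", {
  p <- fx_params()
  p10 <- compensated_perturbation(p, "K_r1", 2)
  expect_equal(unname(wegscheider_residuals(p10)), c(0, 0), tolerance = 1e-12)
  expect_equal(p10$K[["K_r1"]], 2 * p$K[["K_r1"]])
  expect_equal(p10$kf, p$kf)  # forward rates untouched

  expect_identical(compensated_perturbation(p, "K_r1", 1), p)
  back <- compensated_perturbation(
    compensated_perturbation(p, "K_modr", 2), "K_modr", 0.5)
  expect_equal(back$K, p$K, tolerance = 1e-12)

  expect_error(compensated_perturbation(p, "K_s2", 2, "K_s2"), "differ")
  expect_error(compensated_perturbation(p, "K_ii", 2), "not on a closure path")
  expect_error(compensated_perturbation(p, "K_r1", 2, "K_s4"), "same path")
})

test_that("free-energy landscape matches closed-form arithmetic", {
  p <- fx_params()
  # unimolecular step with K = 10 at 303.15 K: dG = -RT ln 10 = -5.80 kJ/mol
  p_s1 <- close_parameters(set_constants(p, K_s1 = 10))
  ls <- energy_landscape(p_s1, temperature_K = 303.15)
  dG_s1 <- ls$dG_kJ_mol[ls$pathway == "PxB_noRDF" & ls$step == "s1"]
  expect_equal(dG_s1, -8.314462618e-3 * 303.15 * log(10), tolerance = 1e-10)
  expect_equal(dG_s1, -5.80, tolerance = 0.01)

  # a step with K_eq equal to its mass-action ratio is isoenergetic
  expect_true(all(abs(ls$dG_kJ_mol[abs(ls$Gamma - ls$K_eq) < 1e-12]) < 1e-9))

  # cumulative pathway dG is zero for a closed set (both pathways)
  for (pw in unique(ls$pathway)) {
    cum <- ls$cumulative_kJ_mol[ls$pathway == pw]
    expect_lt(abs(cum[length(cum)]), 1e-6)
  }

  # |dG| scales linearly in temperature
  ls2 <- energy_landscape(p_s1, temperature_K = 2 * 303.15)
  expect_equal(ls2$dG_kJ_mol, 2 * ls$dG_kJ_mol, tolerance = 1e-10)

  expect_error(energy_landscape(p, ref_dna_nM = 0), "positive")
})

test_that("reference landscape reproduces the qualitative step-sign pattern", {
  ls <- energy_landscape(fx_params())
  sgn <- function(pw, st) ls$sign[ls$pathway == pw & ls$step == st]
  # binding and substrate synapsis favourable; stable-synapse dissociation
  # and final protein release unfavourable
  expect_equal(sgn("PxB_noRDF", "b1"), -1)
  expect_equal(sgn("PxB_noRDF", "s1"), -1)
  expect_equal(sgn("PxB_noRDF", "mod"), -1)
  expect_equal(sgn("PxB_noRDF", "s2"), 1)
  expect_equal(sgn("PxB_noRDF", "b2"), 1)
  expect_equal(sgn("LxR_RDF", "b3"), -1)
  expect_equal(sgn("LxR_RDF", "s4"), 1)
  expect_equal(sgn("LxR_RDF", "b4"), 1)
})

test_that("closure is equivalent to a zero cumulative landscape", {
  # property: random positive parameter sets, closed via K_s2/K_s4, always
  # yield cumulative pathway dG of zero; unclosed sets yield RT * residual
  set.seed(42)
  base <- fx_params()
  for (i in 1:10) {
    K <- base$K * exp(stats::runif(length(base$K), -1, 1))
    p <- close_parameters(rec_params("MODEL1_PLASMID", K, base$kf,
                                     allow_unclosed = TRUE))
    ls <- energy_landscape(p)
    ends <- tapply(ls$cumulative_kJ_mol, ls$pathway, function(x) x[length(x)])
    expect_true(all(abs(ends) < 1e-6))
  }
})
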