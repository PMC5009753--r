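test_that("the objective is zero on self-consistent data and order-invariant", {
  p <- fx_params()
  d <- mini_design()
  ds <- generate_dataset(p, d, noise_sd = 0, seed = 1)
  expect_lt(objective(p, ds), 1e-12)

  ds_noisy <- generate_dataset(p, d, noise_sd = 0.05, seed = 2)
  o1 <- objective(p, ds_noisy)
  perm <- sample(nrow(ds_noisy))
  ds_perm <- ds_noisy[perm, ]
  expect_equal(as.numeric(objective(p, ds_perm)), as.numeric(o1),
               tolerance = 1e-12)

  # unclosed candidates are refused outright
  p_bad <- set_constants(p, K_s2 = p$K[["K_s2"]] * 2)
  expect_error(objective(p_bad, ds), "closed")
})

test_that("swapping substrate labels breaks the fit by orders of magnitude", {
  p <- fx_params()
  ds <- generate_dataset(p, mini_design(), noise_sd = 0, seed = 1)
  ds_sw <- ds
  ds_sw$substrate <- ifelse(ds$substrate == "pPB", "pLR", "pPB")
  ds_sw$rdf_nM <- ifelse(ds$substrate == "pPB", 800, 0)
  # the two permitted reactions' curves are disjoint from the forbidden ones
  expect_gt(objective(p, ds_sw), 1e3 * max(objective(p, ds), 1e-9))
})

test_that("the objective has the chi-square expectation under replicate noise", {
  # one condition, 8 times, replicated 60x in a single dataset: the
  # unweighted SSR of cell means (n = 3 replicates) has expectation
  # n_rows * sd^2 / 3
  p <- fx_params()
  sdv <- 0.03
  base <- data.frame(substrate = "pPB", int_nM = 400, rdf_nM = 0,
                     time_h = c(0.1, 0.25, 0.5, 1, 1.5, 2, 2.5, 3))
  truth <- predict_design(p, base, dna_nM = 10)
  set.seed(99)
  rows <- do.call(rbind, replicate(60, base, simplify = FALSE))
  mu <- rep(truth, 60)
  obs <- vapply(mu, function(m)
    mean(pmin(pmax(m + stats::rnorm(3, 0, sdv), 0), 1)), numeric(1))
  ds <- structure(
    data.frame(rows, fraction_recombinant = obs, sd = sdv, n = 3),
    class = c("experiment_dataset", "data.frame"), dna_nM = 10)
  o <- as.numeric(objective(p, ds))
  expected <- nrow(ds) * sdv^2 / 3
  expect_equal(o, expected, tolerance = 0.15)
})

test_that("noise-free data are a fixed point of the fit, and parameters are
           recovered from a perturbed start", {
  p <- fx_params()
  ds <- generate_dataset(p, mini_design(), noise_sd = 0, seed = 1)

  fit0 <- fit_parameters(ds, p, free_names = c("K_r1", "kf_r1"))
  expect_lt(fit0$objective, 1e-10)
  expect_equal(fit0$params$K[["K_r1"]], p$K[["K_r1"]], tolerance = 1e-6)
  # every reported candidate is closed
  expect_equal(unname(wegscheider_residuals(fit0$params)), c(0, 0),
               tolerance = 1e-12)

  start <- close_parameters(set_constants(
    p, K_r1 = p$K[["K_r1"]] * 1.5, kf_r1 = p$kf[["kf_r1"]] / 1.5))
  fit <- fit_parameters(ds, start, free_names = c("K_r1", "kf_r1"))
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$params$K[["K_r1"]], p$K[["K_r1"]], tolerance = 0.05)
  expect_equal(fit$params$kf[["kf_r1"]], p$kf[["kf_r1"]], tolerance = 0.05)

  expect_error(fit_parameters(ds, p, free_names = c("K_s2")), "derived")
  expect_error(fit_parameters(ds, p, free_names = c("K_nope")), "unknown")
})
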