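test_that("the default design has the calibration study's shape", {
  d <- default_design()
  expect_equal(nrow(d), 92)
  expect_true(all(d$time_h > 0))
  expect_equal(attr(d, "dna_nM"), 10)
  expect_equal(attr(d, "replicates"), 3)
  # each time-course arm includes the 3-h endpoint
  expect_true(any(d$substrate == "pPB" & d$rdf_nM == 0 & d$time_h == 3 &
                    d$int_nM == 400))
  expect_true(any(d$substrate == "pLR" & d$rdf_nM == 800 & d$time_h == 3 &
                    d$int_nM == 400))
  # endpoint grids: integrase dilution series and RDF:integrase ratios
  expect_true(all(c(0.25, 0.5, 1, 2) %in%
                    with(d[d$substrate == "pLR" & d$time_h == 3 &
                             d$rdf_nM > 0, ], unique(rdf_nM / int_nM))))
})

test_that("generation is exactly reproducible from the seed", {
  p <- fx_params()
  d <- mini_design()
  ds1 <- generate_dataset(p, d, seed = 7)
  ds2 <- generate_dataset(p, d, seed = 7)
  expect_identical(ds1$fraction_recombinant, ds2$fraction_recombinant)
  expect_identical(ds1$sd, ds2$sd)
  ds3 <- generate_dataset(p, d, seed = 8)
  expect_false(identical(ds1$fraction_recombinant, ds3$fraction_recombinant))

  # byte-identical CSV round trip
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds1, f1)
  write_dataset(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_dataset(f1)
  expect_equal(back$fraction_recombinant, ds1$fraction_recombinant,
               tolerance = 1e-15)
  expect_match(attr(back, "provenance"), "synthetic\\(7\\)")
})

test_that("zero noise reproduces the model predictions exactly", {
  p <- fx_params()
  d <- mini_design()
  ds <- generate_dataset(p, d, noise_sd = 0, seed = 1)
  expect_equal(ds$fraction_recombinant, fx_mini_truth(), tolerance = 1e-12)
  expect_equal(unique(ds$sd), 0)
})

test_that("the noise generator delivers its nominal sd and respects [0, 1]", {
  p <- fx_params()
  ds <- fixture("full_dataset", function()
    generate_dataset(p, default_design(), seed = 11))
  # pooled replicate variance estimates sd^2 = 0.03^2 away from the [0, 1]
  # bounds, where truncation is negligible
  mid <- attr(ds, "truth") > 0.1 & attr(ds, "truth") < 0.9
  expect_gt(sum(mid), 30)
  expect_equal(sqrt(mean(ds$sd[mid]^2)), 0.03, tolerance = 0.1)
  expect_true(all(ds$fraction_recombinant >= 0 & ds$fraction_recombinant <= 1))

  # heavy noise is truncated, never emitted outside [0, 1]
  ds_wild <- generate_dataset(p, mini_design(), noise_sd = 0.8, seed = 3)
  expect_true(all(ds_wild$fraction_recombinant >= 0 &
                    ds_wild$fraction_recombinant <= 1))
})
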