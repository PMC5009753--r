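# Shared fixtures, memoised so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_params <- function(variant = "MODEL1_PLASMID") {
  fixture(paste0("params_", variant), function() default_parameters(variant))
}

fx_network <- function(variant = "MODEL1_PLASMID") {
  fixture(paste0("net_", variant),
          function() build_network(variant, fx_params(variant)))
}

# a small experiment design (two conditions, five times each) for fitting
# tests where the full 92-cell design would be needlessly slow
mini_design <- function() {
  d <- rbind(
    data.frame(substrate = "pPB", int_nM = 400, rdf_nM = 0,
               time_h = c(0.25, 0.5, 1, 2, 3)),
    data.frame(substrate = "pLR", int_nM = 400, rdf_nM = 800,
               time_h = c(0.25, 0.5, 1, 2, 3)))
  structure(d, class = c("experiment_design", "data.frame"),
            replicates = 3, noise_sd = 0.03, dna_nM = 10)
}

fx_mini_truth <- function() {
  fixture("mini_truth", function() {
    predict_design(fx_params(), mini_design())
  })
}

frac_at <- function(params, substrate, int_nM, rdf_nM, t_s, dna_nM = 10) {
  net <- build_network(params$variant, params)
  y0 <- initial_state(net, substrate, dna_nM, int_nM, rdf_nM)
  fraction_recombinant(simulate_network(net, y0, times = t_s))
}

eq_of <- function(params, substrate, int_nM, rdf_nM, dna_nM = 10) {
  net <- build_network(params$variant, params)
  equilibrium_composition(net, initial_state(net, substrate, dna_nM,
                                             int_nM, rdf_nM))
}
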