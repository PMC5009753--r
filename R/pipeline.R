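# Reproducible pipeline orchestration: one config in, one output bundle out.
# Plain-text, versioned formats only (YAML config, CSV tables, JSON
# reports); every CSV carries a commented metadata header with the package
# version, seed, solver tolerances and a hash of the parameter set.

#' Run the analysis pipeline
#'
#' Orchestrates the tested operations into one reproducible run: echoes the
#' parameter set, simulates the two permitted reactions, computes the
#' free-energy landscape, runs the endpoint concentration scans, finds the
#' equilibrium compositions and (optionally) generates a synthetic dataset
#' and a robustness report. Deterministic given config + seed; identical
#' configs produce byte-identical outputs.
#'
#' @param config either a path to a YAML config file or a list with
#'   components \code{variant}, \code{param_file} (optional; defaults to
#'   [default_parameters()]), \code{out_dir}, \code{seed},
#'   \code{rtol}, \code{atol}, \code{dna_nM}, \code{int_nM}, \code{rdf_nM},
#'   \code{with_synth}, \code{with_robustness}, \code{overwrite}.
#' @return invisibly, the list of files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    variant = "MODEL1_PLASMID", param_file = NULL, out_dir = "intrec_out",
    seed = 1, rtol = .SOLVER_DEFAULTS$rtol, atol = .SOLVER_DEFAULTS$atol,
    dna_nM = 10, int_nM = 400, rdf_nM = 800,
    with_synth = FALSE, with_robustness = FALSE, overwrite = FALSE),
    config)
  for (nm in c("dna_nM", "int_nM", "rdf_nM")) {
    if (cfg[[nm]] < 0) stop("config field ", nm, " must be non-negative")
  }
  params <- if (is.null(cfg$param_file)) default_parameters(cfg$variant)
            else read_params(cfg$param_file)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  meta <- c(
    sprintf("# intrec_version: %s",
            as.character(utils::packageVersion("intrec"))),
    sprintf("# variant: %s", cfg$variant),
    sprintf("# seed: %d", as.integer(cfg$seed)),
    sprintf("# rtol: %g / atol: %g", cfg$rtol, cfg$atol),
    sprintf("# params_hash: %s", .params_hash(params)))
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    if (file.exists(path) && !isTRUE(cfg$overwrite)) {
      stop("output exists (use overwrite: true): ", path)
    }
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(meta, con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }

  files <- character()
  files <- c(files, {
    p <- file.path(cfg$out_dir, "params.yaml")
    if (file.exists(p) && !isTRUE(cfg$overwrite)) {
      stop("output exists (use overwrite: true): ", p)
    }
    write_params(params, p)
  })

  net <- build_network(cfg$variant, params)
  times <- seq(0, 3 * 3600, by = 120)
  if (cfg$variant == "MODEL1_LINEAR") {
    arms <- list(linear_PB = initial_state(net, "linear_PB", cfg$dna_nM,
                                           cfg$int_nM, 0))
  } else {
    arms <- list(
      PxB_noRDF = initial_state(net, "pPB", cfg$dna_nM, cfg$int_nM, 0),
      LxR_RDF = initial_state(net, "pLR", cfg$dna_nM, cfg$int_nM, cfg$rdf_nM))
  }
  tc <- do.call(rbind, lapply(names(arms), function(a) {
    sim <- simulate_network(net, arms[[a]], times[-1],
                            rtol = cfg$rtol, atol = cfg$atol)
    data.frame(reaction = a, time_s = sim$times,
               fraction_recombinant = fraction_recombinant(sim))
  }))
  files <- c(files, emit(tc, "time_courses.csv"))

  eq <- do.call(rbind, lapply(names(arms), function(a) {
    e <- equilibrium_composition(net, arms[[a]])
    data.frame(reaction = a, fraction_recombinant = e$fraction_recombinant,
               max_rhs = e$max_rhs)
  }))
  files <- c(files, emit(eq, "equilibria.csv"))

  files <- c(files,
             emit(as.data.frame(energy_landscape(params)), "landscape.csv"))
  files <- c(files, emit(network_steps(net), "steps.csv"))

  if (cfg$variant != "MODEL1_LINEAR") {
    grid <- 800 / 2^(0:7)
    sc <- rbind(
      concentration_scan(net, "pPB", int_grid = grid, rdf_grid = 0,
                         dna_nM = cfg$dna_nM),
      concentration_scan(net, "pLR", int_grid = cfg$int_nM,
                         rdf_grid = cfg$int_nM * c(0.25, 0.5, 1, 2),
                         dna_nM = cfg$dna_nM))
    files <- c(files, emit(as.data.frame(sc), "scan.csv"))
  }

  if (isTRUE(cfg$with_synth)) {
    ds <- generate_dataset(params, default_design(dna_nM = cfg$dna_nM),
                           seed = cfg$seed)
    p <- file.path(cfg$out_dir, "synthetic_dataset.csv")
    if (file.exists(p) && !isTRUE(cfg$overwrite)) {
      stop("output exists (use overwrite: true): ", p)
    }
    files <- c(files, write_dataset(ds, p))
  }
  if (isTRUE(cfg$with_robustness)) {
    files <- c(files, emit(robustness_scan(params), "robustness.csv"))
  }
  invisible(files)
}

.params_hash <- function(params) {
  v <- c(params$K, params$kf)
  # order- and platform-stable content hash (djb2 over the formatted values)
  s <- paste(names(v), sprintf("%.12e", v), collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
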