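# Experiment-shaped synthetic datasets.
#
# The generator emulates the calibration study's design: triplicate
# time courses of the two permitted reactions (pPB with 400 nM integrase;
# pLR with 400 nM integrase + 800 nM RDF) on 10 nM plasmid, plus 3-h
# endpoint titrations of integrase (pPB) and integrase x RDF (pLR),
# 92 observation cells in total. Replicate noise is additive Gaussian on
# the fraction scale, truncated to [0, 1]; the default sd of 0.03 reflects
# the small triplicate standard deviations of the calibration data and is
# an assumption of the generator, not a measured quantity.

#' Default experiment design
#'
#' Two 16-point time-course arms (2 to 180 min, including the 3-h point)
#' and two 3-h endpoint grids: a 12-point two-fold integrase dilution series
#' from 800 nM for the pPB (-RDF) reaction, and the same series crossed with
#' RDF:integrase ratios 0.25, 0.5, 1 and 2 for the pLR (+RDF) reaction --
#' 92 observation cells, all at 10 nM plasmid, 3 replicates each. The grid
#' values are documented package defaults reconstructing the calibration
#' design.
#'
#' @param dna_nM plasmid concentration (nM).
#' @param replicates replicate count per cell.
#' @param noise_sd Gaussian replicate noise on the fraction scale.
#' @return an \code{experiment_design}: data frame with columns
#'   \code{substrate}, \code{int_nM}, \code{rdf_nM}, \code{time_h}, plus
#'   attributes \code{replicates}, \code{noise_sd}, \code{dna_nM}.
#' @export
default_design <- function(dna_nM = 10, replicates = 3, noise_sd = 0.03) {
  tc_min <- c(2, 5, 10, 15, 20, 30, 45, 60, 75, 90, 105, 120, 135, 150,
              165, 180)
  int_series <- 800 / 2^(0:11)
  rdf_ratio <- c(0.25, 0.5, 1, 2)
  lr_grid <- expand.grid(int_nM = int_series, ratio = rdf_ratio)
  design <- rbind(
    data.frame(substrate = "pPB", int_nM = 400, rdf_nM = 0,
               time_h = tc_min / 60),
    data.frame(substrate = "pLR", int_nM = 400, rdf_nM = 800,
               time_h = tc_min / 60),
    data.frame(substrate = "pPB", int_nM = int_series, rdf_nM = 0,
               time_h = 3),
    data.frame(substrate = "pLR", int_nM = lr_grid$int_nM,
               rdf_nM = lr_grid$int_nM * lr_grid$ratio, time_h = 3)
  )
  rownames(design) <- NULL
  structure(design, class = c("experiment_design", "data.frame"),
            replicates = replicates, noise_sd = noise_sd, dna_nM = dna_nM)
}

#' Generate a synthetic dataset from a model
#'
#' Simulates the given design under Model 1 (or whichever variant
#' \code{params} describes), then draws \code{replicates} noisy observations
#' per cell: fraction + N(0, sd^2), truncated to [0, 1]. The dataset rows
#' carry the replicate mean, the replicate standard deviation and the
#' replicate count; generation is fully reproducible from \code{seed}.
#'
#' @param params a closed \code{rec_params}.
#' @param design an \code{experiment_design} (default [default_design()]).
#' @param noise_sd overrides the design's noise level if not \code{NULL}.
#' @param seed integer RNG seed.
#' @return an \code{experiment_dataset}: data frame with columns
#'   \code{substrate}, \code{int_nM}, \code{rdf_nM}, \code{time_h},
#'   \code{fraction_recombinant}, \code{sd}, \code{n}; attributes
#'   \code{provenance} (\code{"synthetic(seed)"}) and \code{truth}
#'   (noise-free model predictions).
#' @export
generate_dataset <- function(params, design = default_design(),
                             noise_sd = NULL, seed = 1) {
  stopifnot(inherits(params, "rec_params"))
  sdv <- if (is.null(noise_sd)) attr(design, "noise_sd") else noise_sd
  if (sdv < 0) stop("noise_sd must be >= 0")
  reps <- attr(design, "replicates") %||% 3
  pred <- predict_design(params, design)
  set.seed(as.integer(seed))
  obs <- vapply(pred, function(mu) {
    x <- pmin(pmax(mu + stats::rnorm(reps, 0, sdv), 0), 1)
    c(mean(x), stats::sd(x))
  }, numeric(2))
  out <- data.frame(design[, c("substrate", "int_nM", "rdf_nM", "time_h")],
                    fraction_recombinant = obs[1, ],
                    sd = if (reps > 1) obs[2, ] else 0,
                    n = reps)
  structure(out, class = c("experiment_dataset", "data.frame"),
            provenance = sprintf("synthetic(%d)", as.integer(seed)),
            dna_nM = attr(design, "dna_nM") %||% 10,
            truth = pred)
}

#' Model predictions for every cell of a design
#'
#' Groups the design by condition (substrate, integrase, RDF) so each
#' condition is simulated once, reading all requested times off one
#' trajectory.
#'
#' @param params a closed \code{rec_params}.
#' @param design an \code{experiment_design} or any data frame with columns
#'   \code{substrate}, \code{int_nM}, \code{rdf_nM}, \code{time_h}.
#' @param dna_nM plasmid concentration; defaults to the design attribute.
#' @return numeric vector of predicted recombinant fractions, one per row.
#' @export
predict_design <- function(params, design, dna_nM = NULL) {
  stopifnot(inherits(params, "rec_params"))
  dna <- dna_nM %||% attr(design, "dna_nM") %||% 10
  net <- build_network(params$variant, params)
  key <- paste(design$substrate, design$int_nM, design$rdf_nM)
  pred <- numeric(nrow(design))
  for (k in unique(key)) {
    rows <- which(key == k)
    tt <- design$time_h[rows] * 3600
    ord <- order(tt)
    y0 <- initial_state(net, design$substrate[rows[1]], dna,
                        design$int_nM[rows[1]], design$rdf_nM[rows[1]])
    if (design$int_nM[rows[1]] == 0) {
      pred[rows] <- 0
      next
    }
    sim <- simulate_network(net, y0, times = unique(sort(tt)))
    fr <- fraction_recombinant(sim)
    pred[rows] <- fr[match(tt, sim$times)]
  }
  pred
}

# -- dataset file format -------------------------------------------------

#' Read / write experiment datasets
#'
#' CSV with a commented metadata header (\code{# key: value} lines) and the
#' dataset columns \code{substrate}, \code{int_nM}, \code{rdf_nM},
#' \code{time_h}, \code{fraction_recombinant}, \code{sd}, \code{n}. Values
#' round-trip at full double precision.
#'
#' @param dataset an \code{experiment_dataset}.
#' @param path file path.
#' @return \code{read_dataset} returns an \code{experiment_dataset};
#'   \code{write_dataset} returns \code{path} invisibly.
#' @export
write_dataset <- function(dataset, path) {
  meta <- c(sprintf("# provenance: %s",
                    attr(dataset, "provenance") %||% "real"),
            sprintf("# dna_nM: %.17g", attr(dataset, "dna_nM") %||% 10))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("substrate", "int_nM", "rdf_nM", "time_h",
            "fraction_recombinant", "sd", "n")
  if (!all(need %in% names(df))) {
    stop("dataset file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$fraction_recombinant < 0 | df$fraction_recombinant > 1)) {
    stop("fractions outside [0, 1]")
  }
  structure(df, class = c("experiment_dataset", "data.frame"),
            provenance = get_meta("provenance"),
            dna_nM = as.numeric(get_meta("dna_nM")))
}
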