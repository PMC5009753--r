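# Energy conservation (Wegscheider closure) and free-energy landscapes.
#
# Both recombination pathways connect free substrate DNA to free product DNA
# while binding and releasing the same protein complexes; because linear
# substrate and product molecules are isoenergetic, the product of the
# equilibrium constants along each pathway must equal one (equivalently the
# free-energy changes must sum to zero). Statistical binding factors (x2 for
# the first of two identical sites) cancel around each path and are excluded
# from the bookkeeping.

.GAS_R <- 8.314462618e-3  # kJ/(mol K)

#' Wegscheider residuals of a parameter set
#'
#' Computes, for each recombination pathway, the absolute deviation of the
#' signed sum of log equilibrium constants from zero. A residual of zero
#' means that free substrate and free product DNA are isoenergetic given the
#' step constants; both residuals must vanish for a thermodynamically
#' admissible ("closed") parameter set.
#'
#' The -RDF path runs free pPB -> ... -> free pLR through steps
#' b1 (twice), s1, r1, (mod,) s2, b2 (twice, as dissociation); the +RDF path
#' runs free pLR -> ... -> free pPB through b3, s3, r2, (modr,) s4, b4.
#' \code{K_s2} and \code{K_s4} enter in the desynapsis direction, the
#' direction the product pathway traverses them.
#'
#' @param params a \code{rec_params} (closed or not).
#' @return named numeric vector \code{c(noRDF = ..., RDF = ...)} of
#'   absolute log-space residuals. The RDF component is 0 for the linear
#'   variant, which models only the -RDF pathway.
#' @export
wegscheider_residuals <- function(params) {
  stopifnot(inherits(params, "rec_params"))
  paths <- .CLOSURE_PATHS[[params$variant]]
  res <- vapply(paths, function(pp) {
    if (is.null(pp)) return(0)
    abs(sum(pp * log(params$K[names(pp)])))
  }, numeric(1))
  c(noRDF = unname(res["noRDF"]),
    RDF = if (is.null(paths$RDF)) 0 else unname(res["RDF"]))
}

#' Close a parameter set under Wegscheider's condition
#'
#' Recomputes the named derived constants so that both pathway residuals are
#' exactly zero, leaving every other equilibrium constant and every forward
#' rate unchanged (reverse rates are always rederived as \code{kf / K}).
#'
#' The default derived constants are \code{K_s2} (-RDF path) and \code{K_s4}
#' (+RDF path): the desynapsis constants of the kinetically stable product
#' synapses, which are the least directly constrained by data and through
#' which perturbation analyses are conventionally compensated.
#'
#' @param params a \code{rec_params}.
#' @param derive character vector naming one constant per pathway to solve
#'   for; each must appear exactly once in its pathway.
#' @return a closed \code{rec_params}.
#' @export
close_parameters <- function(params,
                             derive = c("K_s2", "K_s4")) {
  stopifnot(inherits(params, "rec_params"))
  K <- params$K
  paths <- .CLOSURE_PATHS[[params$variant]]
  for (pp in paths) {
    if (is.null(pp)) next
    nm <- intersect(derive, names(pp))
    if (length(nm) == 0) next
    if (length(nm) > 1) {
      stop("more than one derived constant on the same path: ",
           paste(nm, collapse = ", "))
    }
    if (abs(pp[[nm]]) != 1) {
      stop("derived constant ", nm, " must appear exactly once in its path")
    }
    others <- setdiff(names(pp), nm)
    logK <- -sum(pp[others] * log(K[others])) / pp[[nm]]
    K[[nm]] <- exp(logK)
  }
  out <- rec_params(params$variant, K, params$kf, allow_unclosed = TRUE,
                    tetramer_inhibition = params$tetramer_inhibition)
  res <- wegscheider_residuals(out)
  if (any(res > 1e-9)) {
    stop("closure failed: no derived constant on a non-zero-residual path ",
         "(residuals ", paste(signif(res, 3), collapse = ", "), ")")
  }
  out
}

#' Apply a compensated perturbation
#'
#' Multiplies one equilibrium constant by \code{fold} and recomputes a
#' compensating constant on the same pathway so that energy conservation is
#' preserved. All other constants and all forward rates are unchanged. This
#' is the operation behind "what if strand exchange (or synapse
#' modification) were more favourable" predictions: e.g. doubling
#' \code{K_r1} with compensation through \code{K_s2} raises the equilibrium
#' product yield of the attP x attB reaction.
#'
#' @param params a closed \code{rec_params}.
#' @param target name of the constant to perturb.
#' @param fold multiplicative factor (> 0); \code{fold = 1} returns the
#'   input unchanged.
#' @param compensator name of the constant adjusted to restore closure
#'   (default \code{"K_s2"} for -RDF-path targets, \code{"K_s4"} for
#'   +RDF-path targets).
#' @return a closed \code{rec_params}.
#' @export
compensated_perturbation <- function(params, target, fold,
                                     compensator = NULL) {
  stopifnot(inherits(params, "rec_params"), fold > 0)
  paths <- .CLOSURE_PATHS[[params$variant]]
  on_no <- !is.null(paths$noRDF) && target %in% names(paths$noRDF)
  on_rdf <- !is.null(paths$RDF) && target %in% names(paths$RDF)
  if (!on_no && !on_rdf) stop("target ", target, " is not on a closure path")
  if (is.null(compensator)) compensator <- if (on_no) "K_s2" else "K_s4"
  if (identical(target, compensator)) {
    stop("target and compensator must differ")
  }
  path <- if (on_no) paths$noRDF else paths$RDF
  if (!compensator %in% names(path)) {
    stop("compensator ", compensator, " is not on the same path as ", target)
  }
  if (fold == 1) return(params)
  p2 <- set_constants(params, stats::setNames(params$K[[target]] * fold,
                                              target))
  close_parameters(p2, derive = compensator)
}

# Energy landscape -------------------------------------------------------

#' Per-step Gibbs free-energy landscape of the recombination pathways
#'
#' For each named pathway step the free-energy change is
#' \eqn{\Delta G = RT \ln(\Gamma / K_{eq})}, where \eqn{\Gamma} is the
#' mass-action ratio evaluated with every DNA-containing species at
#' \code{ref_dna_nM} and every unbound protein complex (integrase dimer or
#' integrase--RDF complex) at \code{ref_protein_nM}. Binding steps are
#' reported for the complete loading of both att sites (two dimers), so the
#' -RDF pathway reads b1, s1, r1, (mod,) s2, b2 and the +RDF pathway
#' b3, s3, r2, (modr,) s4, b4; for a closed parameter set each pathway's
#' cumulative \eqn{\Delta G} is zero, the landscape expression of energy
#' conservation.
#'
#' @param params a closed \code{rec_params}.
#' @param ref_dna_nM reference concentration of DNA-containing species (nM).
#' @param ref_protein_nM reference concentration of unbound protein
#'   complexes (nM).
#' @param temperature_K absolute temperature; default 303.15 K (30 C, the
#'   reaction incubation temperature).
#' @return an object of class \code{energy_landscape}: a data frame with
#'   columns \code{pathway}, \code{step}, \code{K_eq}, \code{Gamma},
#'   \code{dG_kJ_mol}, \code{sign} and \code{cumulative_kJ_mol}, with the
#'   reference conditions stored as attributes.
#' @export
energy_landscape <- function(params, ref_dna_nM = 10, ref_protein_nM = 200,
                             temperature_K = 303.15) {
  stopifnot(inherits(params, "rec_params"))
  if (ref_dna_nM <= 0 || ref_protein_nM <= 0) {
    stop("reference concentrations must be positive")
  }
  res <- wegscheider_residuals(params)
  if (any(res > 1e-9)) {
    stop("energy_landscape requires a closed parameter set")
  }
  RT <- .GAS_R * temperature_K
  K <- params$K
  P <- ref_protein_nM
  model1 <- params$variant %in% c("MODEL1_PLASMID", "MODEL1_LINEAR")

  # step table: K_eq and Gamma per pathway transition (DNA concentrations
  # cancel in unimolecular transitions between DNA species)
  steps_no <- list(
    b1 = list(K = K[["K_b1"]]^2, G = 1 / P^2),
    s1 = list(K = K[["K_s1"]],
              G = if (params$variant == "MODEL1_LINEAR") 1 / ref_dna_nM else 1),
    r1 = list(K = K[["K_r1"]], G = 1)
  )
  if (model1) steps_no$mod <- list(K = K[["K_mod"]], G = 1)
  steps_no$s2 <- list(K = K[["K_s2"]],
                      G = if (params$variant == "MODEL1_LINEAR") ref_dna_nM else 1)
  steps_no$b2 <- list(K = 1 / K[["K_b2"]]^2, G = P^2)

  tab <- .landscape_rows("PxB_noRDF", steps_no, RT)
  if (params$variant != "MODEL1_LINEAR") {
    steps_r <- list(
      b3 = list(K = K[["K_b3"]]^2, G = 1 / P^2),
      s3 = list(K = K[["K_s3"]], G = 1),
      r2 = list(K = K[["K_r2"]], G = 1)
    )
    if (model1) steps_r$modr <- list(K = K[["K_modr"]], G = 1)
    steps_r$s4 <- list(K = K[["K_s4"]], G = 1)
    steps_r$b4 <- list(K = 1 / K[["K_b4"]]^2, G = P^2)
    tab <- rbind(tab, .landscape_rows("LxR_RDF", steps_r, RT))
  }
  structure(tab,
            class = c("energy_landscape", "data.frame"),
            ref_dna_nM = ref_dna_nM, ref_protein_nM = ref_protein_nM,
            temperature_K = temperature_K)
}

.landscape_rows <- function(pathway, steps, RT) {
  dG <- vapply(steps, function(s) RT * log(s$G / s$K), numeric(1))
  data.frame(
    pathway = pathway,
    step = names(steps),
    K_eq = vapply(steps, `[[`, numeric(1), "K"),
    Gamma = vapply(steps, `[[`, numeric(1), "G"),
    dG_kJ_mol = unname(dG),
    sign = sign(round(unname(dG), 9)),
    cumulative_kJ_mol = cumsum(unname(dG)),
    row.names = NULL
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape (T = %.2f K, DNA %.3g nM, protein %.3g nM)\n",
              attr(x, "temperature_K"), attr(x, "ref_dna_nM"),
              attr(x, "ref_protein_nM")))
  print.data.frame(cbind(x[, c("pathway", "step")],
                         round(x[, c("dG_kJ_mol", "cumulative_kJ_mol")], 2)))
  invisible(x)
}

#' Export an energy landscape to CSV or JSON
#'
#' @param landscape an \code{energy_landscape}.
#' @param path output file; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(reference = list(dna_nM = attr(landscape, "ref_dna_nM"),
                            protein_nM = attr(landscape, "ref_protein_nM"),
                            temperature_K = attr(landscape, "temperature_K")),
           steps = as.data.frame(landscape)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(landscape), path, row.names = FALSE)
  }
  invisible(path)
}
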