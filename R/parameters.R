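# Model variants ---------------------------------------------------------

#' Model variants
#'
#' Three variants of the recombination kinetic model are supported:
#' \describe{
#'   \item{\code{MODEL0_PLASMID}}{The minimal scheme for intramolecular
#'     recombination on a supercoiled plasmid: integrase (or integrase--RDF)
#'     binding, synapsis, strand exchange and desynapsis, with no
#'     post-exchange synapse modification step.}
#'   \item{\code{MODEL1_PLASMID}}{The full scheme, adding kinetically stable
#'     product synapses (\code{LR_int_s2}, \code{PB_intrdf_s2}) reached by a
#'     conformational modification step (\code{mod}, \code{modr}), with slow
#'     synapsis/desynapsis of these stable complexes.}
#'   \item{\code{MODEL1_LINEAR}}{The full scheme adapted to intermolecular
#'     recombination between short linear attP and attB fragments: binding is
#'     per fragment, synapsis is bimolecular, and strand exchange is slower
#'     than on a supercoiled plasmid. Only the -RDF (attP x attB) pathway is
#'     modelled for linear substrates.}
#' }
#' @name variants
#' @keywords internal
NULL

.VARIANTS <- c("MODEL0_PLASMID", "MODEL1_PLASMID", "MODEL1_LINEAR")

# Equilibrium-constant and forward-rate names per variant.
# Units: concentrations in nM, time in s.
#   K_b*   per-site association constants, 1/nM
#   K_s*   synapsis constants (dimensionless for plasmids; K_s1 in 1/nM and
#          K_s2 in nM for the linear variant). K_s2 and K_s4 are named in the
#          DESYNAPSIS direction (stable product synapse -> desynapsed
#          complex); see close_parameters().
#   K_r*, K_mod*  dimensionless
#   K_ii, K_ir    solution dissociation constants, nM
#   K_inh  association constant of a second integrase dimer onto an occupied
#          attP/attB site (synapsis-blocked tetramer site), 1/nM
.K_NAMES <- list(
  MODEL0_PLASMID = c("K_b1", "K_b2", "K_b3", "K_b4", "K_s1", "K_s2", "K_s3",
                     "K_s4", "K_r1", "K_r2", "K_ii", "K_ir", "K_inh"),
  MODEL1_PLASMID = c("K_b1", "K_b2", "K_b3", "K_b4", "K_s1", "K_s2", "K_s3",
                     "K_s4", "K_r1", "K_r2", "K_mod", "K_modr", "K_ii",
                     "K_ir", "K_inh"),
  MODEL1_LINEAR  = c("K_b1", "K_b2", "K_s1", "K_s2", "K_r1", "K_mod",
                     "K_ii", "K_inh")
)

.KF_NAMES <- lapply(.K_NAMES, function(k) sub("^K_", "kf_", k))

# Closure paths: signed log-sums that must vanish for an energy-conserving
# parameter set (substrate and product DNA are isoenergetic, the same protein
# complexes are bound and released). Statistical binding factors cancel
# around each path and are excluded.
.CLOSURE_PATHS <- list(
  MODEL0_PLASMID = list(
    noRDF = c(K_b1 = 2, K_s1 = 1, K_r1 = 1, K_s2 = 1, K_b2 = -2),
    RDF   = c(K_b3 = 2, K_s3 = 1, K_r2 = 1, K_s4 = 1, K_b4 = -2)
  ),
  MODEL1_PLASMID = list(
    noRDF = c(K_b1 = 2, K_s1 = 1, K_r1 = 1, K_mod = 1, K_s2 = 1, K_b2 = -2),
    RDF   = c(K_b3 = 2, K_s3 = 1, K_r2 = 1, K_modr = 1, K_s4 = 1, K_b4 = -2)
  ),
  MODEL1_LINEAR = list(
    noRDF = c(K_b1 = 2, K_s1 = 1, K_r1 = 1, K_mod = 1, K_s2 = 1, K_b2 = -2),
    RDF   = NULL
  )
)

# ParameterSet -----------------------------------------------------------

#' Create a parameter set for a recombination model variant
#'
#' A \code{rec_params} object holds the named equilibrium constants and
#' forward rate constants of one model variant. Reverse rate constants are
#' never stored: for every step \code{kr = kf / K}, so that each equilibrium
#' constant is exactly the ratio of forward to reverse rate constant.
#'
#' Units follow the nM / second convention throughout: per-site association
#' constants \code{K_b*} and the linear-variant \code{K_s1} are in 1/nM,
#' solution dissociation constants \code{K_ii} and \code{K_ir} in nM,
#' bimolecular forward rates in 1/(nM s) and unimolecular rates in 1/s.
#'
#' The synapsis constants of the stable product synapses, \code{K_s2} and
#' \code{K_s4}, are named in the \emph{desynapsis} direction (e.g.
#' \code{LR_int_s2 -> LR_int}), matching the direction the product pathway
#' traverses them. Getting this convention wrong silently breaks energy
#' conservation, so it is asserted in the closure arithmetic and documented
#' here prominently.
#'
#' @param variant one of \code{"MODEL0_PLASMID"}, \code{"MODEL1_PLASMID"},
#'   \code{"MODEL1_LINEAR"}.
#' @param K named numeric vector of equilibrium constants (see
#'   \code{required_constants}).
#' @param kf named numeric vector of forward rate constants, one per step.
#' @param allow_unclosed if \code{TRUE}, a parameter set whose Wegscheider
#'   residuals are non-zero is accepted (diagnostic use only, e.g. to
#'   reproduce what goes wrong without energy conservation). Default
#'   \code{FALSE}: construction fails unless both residuals are below
#'   \code{1e-9} in natural-log space.
#' @param tetramer_inhibition logical; include formation of synapsis-blocked
#'   integrase tetramers at occupied attP/attB sites (default \code{TRUE}).
#'
#' @return an object of class \code{rec_params}.
#' @seealso [close_parameters()], [default_parameters()],
#'   [wegscheider_residuals()]
#' @export
rec_params <- function(variant, K, kf, allow_unclosed = FALSE,
                       tetramer_inhibition = TRUE) {
  variant <- match.arg(variant, .VARIANTS)
  needK <- .K_NAMES[[variant]]
  needkf <- .KF_NAMES[[variant]]
  missK <- setdiff(needK, names(K))
  misskf <- setdiff(needkf, names(kf))
  if (length(missK) || length(misskf)) {
    stop("missing constants for ", variant, ": ",
         paste(c(missK, misskf), collapse = ", "))
  }
  K <- K[needK]
  kf <- kf[needkf]
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("all equilibrium constants must be positive and finite")
  }
  if (any(!is.finite(kf)) || any(kf <= 0)) {
    stop("all forward rate constants must be positive and finite")
  }
  p <- structure(
    list(variant = variant, K = K, kf = kf,
         tetramer_inhibition = isTRUE(tetramer_inhibition)),
    class = "rec_params"
  )
  if (!allow_unclosed) {
    res <- wegscheider_residuals(p)
    if (any(res > 1e-9)) {
      stop("parameter set violates energy conservation (Wegscheider ",
           "residuals ", paste(signif(res, 3), collapse = ", "),
           "); use close_parameters() or allow_unclosed = TRUE")
    }
  }
  p
}

#' @export
print.rec_params <- function(x, ...) {
  cat("<rec_params>", x$variant, "\n")
  res <- wegscheider_residuals(x)
  cat("  Wegscheider residuals (|sum log K|):",
      paste(sprintf("%s = %.3g", names(res), res), collapse = ", "), "\n")
  cat("  Equilibrium constants:\n")
  print(signif(x$K, 4))
  cat("  Forward rate constants:\n")
  print(signif(x$kf, 4))
  invisible(x)
}

#' Names of the constants required by a model variant
#'
#' @param variant model variant string.
#' @return list with components \code{K} and \code{kf}.
#' @export
required_constants <- function(variant) {
  variant <- match.arg(variant, .VARIANTS)
  list(K = .K_NAMES[[variant]], kf = .KF_NAMES[[variant]])
}

#' Reverse rate constants implied by a parameter set
#'
#' For every step \code{kr = kf / K} exactly.
#'
#' @param params a \code{rec_params} object.
#' @return named numeric vector of reverse rates (names \code{kr_*}).
#' @export
reverse_rates <- function(params) {
  stopifnot(inherits(params, "rec_params"))
  kr <- params$kf / params$K[sub("^kf_", "K_", names(params$kf))]
  names(kr) <- sub("^kf_", "kr_", names(params$kf))
  kr
}

#' Replace constants in a parameter set
#'
#' Returns a copy of \code{params} with the named equilibrium or forward-rate
#' constants replaced. No closure is performed; combine with
#' \code{\link{close_parameters}} to restore energy conservation.
#'
#' @param params a \code{rec_params}.
#' @param ... named scalar replacements, e.g. \code{K_r1 = 0.5}.
#' @param allow_unclosed passed to the reconstructed object.
#' @return a \code{rec_params}.
#' @export
set_constants <- function(params, ..., allow_unclosed = TRUE) {
  repl <- c(...)
  K <- params$K
  kf <- params$kf
  for (nm in names(repl)) {
    if (nm %in% names(K)) K[[nm]] <- repl[[nm]]
    else if (nm %in% names(kf)) kf[[nm]] <- repl[[nm]]
    else stop("unknown constant: ", nm)
  }
  rec_params(params$variant, K, kf, allow_unclosed = allow_unclosed,
             tetramer_inhibition = params$tetramer_inhibition)
}

# Default (reference) parameters -----------------------------------------

#' Reference parameter sets
#'
#' Returns the package's reference parameter set for a model variant. The
#' values were calibrated against the reported outcomes of in vitro
#' recombination of 10 nM plasmid substrate by 400 nM integrase (with 800 nM
#' RDF for the attL x attR reaction): the 30-min and equilibrium extents of
#' the permitted reactions, the very slow approach to equilibrium of the
#' non-permitted reactions, and the 3-h extent of recombination between
#' linear attP/attB fragments. See the package vignette for the calibration
#' procedure and the role of each constant.
#'
#' The sets returned are closed under Wegscheider's condition: \code{K_s2}
#' (and \code{K_s4} for plasmid variants) are derived from the other
#' constants of their pathway by [close_parameters()].
#'
#' @param variant model variant string (default \code{"MODEL1_PLASMID"}).
#' @return a closed \code{rec_params}.
#' @export
default_parameters <- function(variant = "MODEL1_PLASMID") {
  variant <- match.arg(variant, .VARIANTS)
  p <- switch(variant,
    MODEL1_PLASMID = {
      K <- c(K_b1 = 0.1, K_b2 = 0.2, K_b3 = 0.2, K_b4 = 0.1,
             K_s1 = 20, K_s2 = 1, K_s3 = 3.5, K_s4 = 1,
             K_r1 = 0.622, K_r2 = 0.518, K_mod = 4.2, K_modr = 4.0,
             K_ii = 10, K_ir = 5, K_inh = 0.003)
      kf <- c(kf_b1 = 0.01, kf_b2 = 0.01, kf_b3 = 0.01, kf_b4 = 0.01,
              kf_s1 = 0.05, kf_s2 = 1e-7, kf_s3 = 0.05, kf_s4 = 1.43e-6,
              kf_r1 = 2.73e-3, kf_r2 = 3.45e-3, kf_mod = 2.73e-3,
              kf_modr = 3.45e-3,
              kf_ii = 0.01, kf_ir = 0.01, kf_inh = 0.001)
      rec_params(variant, K, kf, allow_unclosed = TRUE)
    },
    MODEL0_PLASMID = {
      K <- c(K_b1 = 0.1, K_b2 = 0.2, K_b3 = 0.2, K_b4 = 0.1,
             K_s1 = 20, K_s2 = 1, K_s3 = 3.5, K_s4 = 1,
             K_r1 = 3.0, K_r2 = 2.0,
             K_ii = 10, K_ir = 5, K_inh = 0.003)
      kf <- c(kf_b1 = 0.01, kf_b2 = 0.01, kf_b3 = 0.01, kf_b4 = 0.01,
              kf_s1 = 0.05, kf_s2 = 0.01, kf_s3 = 0.05, kf_s4 = 0.01,
              kf_r1 = 0.004, kf_r2 = 0.004,
              kf_ii = 0.01, kf_ir = 0.01, kf_inh = 0.001)
      rec_params(variant, K, kf, allow_unclosed = TRUE)
    },
    MODEL1_LINEAR = {
      K <- c(K_b1 = 0.1, K_b2 = 0.2, K_s1 = 0.15, K_s2 = 1,
             K_r1 = 0.622, K_mod = 4.2, K_ii = 10, K_inh = 0.003)
      kf <- c(kf_b1 = 0.01, kf_b2 = 0.01, kf_s1 = 0.001, kf_s2 = 1e-7,
              kf_r1 = 1.11e-3, kf_mod = 1.11e-3, kf_ii = 0.01,
              kf_inh = 0.001)
      rec_params(variant, K, kf, allow_unclosed = TRUE)
    }
  )
  close_parameters(p)
}

# Parameter file I/O -----------------------------------------------------

#' Read / write parameter files
#'
#' Parameters are stored as a flat YAML document with a \code{variant} tag
#' and the exact constant names of [required_constants()]. The loader
#' validates completeness and (unless \code{allow_unclosed}) energy
#' conservation.
#'
#' @param path file path.
#' @param params a \code{rec_params}.
#' @param allow_unclosed accept an unclosed set (diagnostic).
#' @return \code{read_params} returns a \code{rec_params};
#'   \code{write_params} returns \code{path} invisibly.
#' @export
read_params <- function(path, allow_unclosed = FALSE) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$variant)) stop("parameter file lacks a 'variant' field")
  vals <- unlist(doc[setdiff(names(doc), c("variant", "tetramer_inhibition"))])
  rec_params(doc$variant,
             K = vals[grep("^K_", names(vals))],
             kf = vals[grep("^kf_", names(vals))],
             allow_unclosed = allow_unclosed,
             tetramer_inhibition = doc$tetramer_inhibition %||% TRUE)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "rec_params"))
  doc <- c(list(variant = params$variant,
                tetramer_inhibition = params$tetramer_inhibition),
           as.list(params$K), as.list(params$kf))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
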