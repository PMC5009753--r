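# Reaction-network construction.
#
# Species bookkeeping: each plasmid carries two att sites in inverted
# repeat; a site is either empty (E), bound by an integrase dimer (I), by a
# half-loaded integrase-RDF complex int2rdf1 (R1), by the fully loaded
# int2rdf2 (R2), or blocked by an integrase tetramer (T; two dimers, formed
# by association of a second dimer from solution, synapsis-incompetent).
# Plasmid species are unordered pairs of site states on a PB or LR DNA
# configuration, plus the synaptic complexes of the two pathways. Binding
# uses sequential per-site steps with the standard statistical factors for
# two identical sites (first dimer on at 2 kf, second at kf; reverse
# symmetric), honouring the equal-affinity assumption: one per-site constant
# per substrate and ligand class.

.SOL_SPECIES <- data.frame(
  name = c("int", "int2", "rdf", "int2rdf1", "int2rdf2"),
  n_int = c(1, 2, 0, 2, 2),
  n_rdf = c(0, 0, 1, 1, 2),
  stringsAsFactors = FALSE
)

.SITE_INT <- c(E = 0, I = 2, R1 = 2, R2 = 2, T = 4)
.SITE_RDF <- c(E = 0, I = 0, R1 = 1, R2 = 2, T = 0)
.LIGAND <- c(I = "int2", R1 = "int2rdf1", R2 = "int2rdf2")

.pair_name <- function(cfg, pair) {
  key <- paste(sort(pair), collapse = "")
  switch(key,
    "EE"   = cfg,
    "EI"   = paste0(cfg, "_int1"),
    "II"   = paste0(cfg, "_int"),
    "ER2"  = paste0(cfg, "_intrdf1"),
    "R2R2" = paste0(cfg, "_intrdf"),
    paste0(cfg, "_", paste(sort(pair), collapse = "."))
  )
}

#' Build the reaction network of a model variant
#'
#' Assembles the full species list and reversible mass-action step list for
#' one model variant, given a parameter set. Every step is reversible
#' (\code{kr = kf / K}) and no step is of higher than second order. The
#' returned network carries the stoichiometry matrix and the linear
#' conservation laws (total DNA, total integrase monomers, total RDF
#' monomers) used to audit simulations.
#'
#' @param variant model variant string; must match \code{params$variant}.
#' @param params a \code{rec_params}; must be closed unless
#'   \code{allow_unclosed}.
#' @param allow_unclosed build from an unclosed parameter set (diagnostic
#'   reproduction of energy-conservation violations).
#' @return an object of class \code{rec_network} with components
#'   \code{species} (data frame: name, composition counts, DNA
#'   configuration), \code{steps} (data frame: name, reactants, products,
#'   kf, kr), \code{stoich} (species x steps matrix), and
#'   \code{conservation} (laws x species matrix).
#' @export
build_network <- function(variant, params, allow_unclosed = FALSE) {
  variant <- match.arg(variant, .VARIANTS)
  stopifnot(inherits(params, "rec_params"))
  if (!identical(params$variant, variant)) {
    stop("params$variant (", params$variant, ") does not match ", variant)
  }
  res <- wegscheider_residuals(params)
  if (!allow_unclosed && any(res > 1e-9)) {
    stop("parameter set is not closed (residuals ",
         paste(signif(res, 3), collapse = ", "),
         "); close_parameters() it or pass allow_unclosed = TRUE")
  }
  if (variant == "MODEL1_LINEAR") {
    .build_linear(params)
  } else {
    .build_plasmid(params, model1 = variant == "MODEL1_PLASMID")
  }
}

# -- plasmid variants ----------------------------------------------------

.build_plasmid <- function(params, model1) {
  K <- params$K; kf <- params$kf
  inh <- params$tetramer_inhibition

  site_states <- list(
    PB = c("E", "I", "R1", "R2", if (inh) "T"),
    LR = c("E", "I", "R1", "R2")
  )
  # per-site binding constants by configuration and bound state
  siteK <- list(PB = c(I = K[["K_b1"]], R1 = K[["K_b4"]], R2 = K[["K_b4"]]),
                LR = c(I = K[["K_b2"]], R1 = K[["K_b3"]], R2 = K[["K_b3"]]))
  sitekf <- list(PB = c(I = kf[["kf_b1"]], R1 = kf[["kf_b4"]], R2 = kf[["kf_b4"]]),
                 LR = c(I = kf[["kf_b2"]], R1 = kf[["kf_b3"]], R2 = kf[["kf_b3"]]))
  stepbase <- list(PB = c(I = "b1", R1 = "b4", R2 = "b4"),
                   LR = c(I = "b2", R1 = "b3", R2 = "b3"))

  species <- .SOL_SPECIES
  species$config <- NA_character_
  pairs <- list()
  for (cfg in c("PB", "LR")) {
    st <- site_states[[cfg]]
    for (i in seq_along(st)) for (j in i:length(st)) {
      pair <- c(st[i], st[j])
      pairs[[length(pairs) + 1]] <- list(cfg = cfg, pair = pair)
      species <- rbind(species, data.frame(
        name = .pair_name(cfg, pair),
        n_int = sum(.SITE_INT[pair]), n_rdf = sum(.SITE_RDF[pair]),
        config = cfg, stringsAsFactors = FALSE))
    }
  }
  syn <- data.frame(
    name = c("PB_int_s", "LR_int_s1", if (model1) "LR_int_s2",
             "LR_intrdf_s", "PB_intrdf_s1", if (model1) "PB_intrdf_s2"),
    stringsAsFactors = FALSE)
  syn$n_int <- 4
  syn$n_rdf <- ifelse(grepl("rdf", syn$name), 4, 0)
  syn$config <- ifelse(grepl("^PB", syn$name), "PB", "LR")
  species <- rbind(species, syn)
  species$n_dna <- as.integer(!is.na(species$config))

  steps <- list()
  add <- function(name, reactants, products, kf, kr) {
    steps[[length(steps) + 1]] <<- list(name = name, r = reactants,
                                        p = products, kf = kf, kr = kr)
  }

  # solution complexation: dimerization and sequential RDF loading
  add("ii", c("int", "int"), "int2", kf[["kf_ii"]], kf[["kf_ii"]] * K[["K_ii"]])
  add("ir.1", c("int2", "rdf"), "int2rdf1",
      2 * kf[["kf_ir"]], kf[["kf_ir"]] * K[["K_ir"]])
  add("ir.2", c("int2rdf1", "rdf"), "int2rdf2",
      kf[["kf_ir"]], 2 * kf[["kf_ir"]] * K[["K_ir"]])

  # per-site binding (sequential, statistical factors), all ligand classes
  for (pp in pairs) {
    cfg <- pp$cfg; pair <- sort(pp$pair)
    n_empty <- sum(pair == "E")
    if (n_empty == 0) next
    for (lig in names(.LIGAND)) {
      target <- sort(c(setdiff2(pair, "E"), lig))
      mult_f <- n_empty
      mult_r <- sum(target == lig)
      k1 <- sitekf[[cfg]][[lig]]
      add(paste0(stepbase[[cfg]][[lig]], ":", .pair_name(cfg, pair), "+",
                 .LIGAND[[lig]]),
          c(.pair_name(cfg, pair), .LIGAND[[lig]]),
          .pair_name(cfg, target),
          mult_f * k1, mult_r * k1 / siteK[[cfg]][[lig]])
    }
  }

  # tetramer inhibition: second dimer joins an occupied attP/attB site
  if (inh) {
    for (pp in pairs) {
      if (pp$cfg != "PB") next
      pair <- sort(pp$pair)
      n_I <- sum(pair == "I")
      if (n_I == 0) next
      target <- sort(c(setdiff2(pair, "I"), "T"))
      mult_r <- sum(target == "T")
      add(paste0("inh:", .pair_name("PB", pair)),
          c(.pair_name("PB", pair), "int2"), .pair_name("PB", target),
          n_I * kf[["kf_inh"]], mult_r * kf[["kf_inh"]] / K[["K_inh"]])
    }
  }

  # pathway: synapsis, strand exchange, synapse modification, desynapsis.
  # s2 and s4 are written in the desynapsis direction (stable product
  # synapse -> desynapsed complex), matching the K_s2/K_s4 convention.
  uni <- function(name, from, to, kfv, Kv) add(name, from, to, kfv, kfv / Kv)
  uni("s1", "PB_int", "PB_int_s", kf[["kf_s1"]], K[["K_s1"]])
  uni("r1", "PB_int_s", "LR_int_s1", kf[["kf_r1"]], K[["K_r1"]])
  if (model1) {
    uni("mod", "LR_int_s1", "LR_int_s2", kf[["kf_mod"]], K[["K_mod"]])
    uni("s2", "LR_int_s2", "LR_int", kf[["kf_s2"]], K[["K_s2"]])
  } else {
    uni("s2", "LR_int_s1", "LR_int", kf[["kf_s2"]], K[["K_s2"]])
  }
  uni("s3", "LR_intrdf", "LR_intrdf_s", kf[["kf_s3"]], K[["K_s3"]])
  uni("r2", "LR_intrdf_s", "PB_intrdf_s1", kf[["kf_r2"]], K[["K_r2"]])
  if (model1) {
    uni("modr", "PB_intrdf_s1", "PB_intrdf_s2", kf[["kf_modr"]], K[["K_modr"]])
    uni("s4", "PB_intrdf_s2", "PB_intrdf", kf[["kf_s4"]], K[["K_s4"]])
  } else {
    uni("s4", "PB_intrdf_s1", "PB_intrdf", kf[["kf_s4"]], K[["K_s4"]])
  }

  .assemble_network(params, species, steps,
                    substrates = c(pPB = "PB", pLR = "LR"))
}

# -- linear variant ------------------------------------------------------

.build_linear <- function(params) {
  K <- params$K; kf <- params$kf
  inh <- params$tetramer_inhibition
  species <- .SOL_SPECIES[.SOL_SPECIES$name %in% c("int", "int2"), ]
  species$config <- NA_character_
  frag <- data.frame(
    name = c("attP", "attB", "attL", "attR",
             "attP_int", "attB_int", "attL_int", "attR_int",
             if (inh) c("attP_T", "attB_T"),
             "PB_s", "LR_s1", "LR_s2"),
    stringsAsFactors = FALSE)
  frag$n_int <- c(0, 0, 0, 0, 2, 2, 2, 2, if (inh) c(4, 4), 4, 4, 4)
  frag$n_rdf <- 0
  frag$config <- c("P", "B", "L", "R", "P", "B", "L", "R",
                   if (inh) c("P", "B"), "S", "SL", "SL")
  species <- rbind(species, frag)
  species$n_dna <- as.integer(!is.na(species$config))

  steps <- list()
  add <- function(name, reactants, products, kfv, krv) {
    steps[[length(steps) + 1]] <<- list(name = name, r = reactants,
                                        p = products, kf = kfv, kr = krv)
  }
  add("ii", c("int", "int"), "int2", kf[["kf_ii"]],
      kf[["kf_ii"]] * K[["K_ii"]])
  for (f in c("attP", "attB")) {
    add(paste0("b1:", f), c(f, "int2"), paste0(f, "_int"),
        kf[["kf_b1"]], kf[["kf_b1"]] / K[["K_b1"]])
  }
  for (f in c("attL", "attR")) {
    add(paste0("b2:", f), c(f, "int2"), paste0(f, "_int"),
        kf[["kf_b2"]], kf[["kf_b2"]] / K[["K_b2"]])
  }
  if (inh) {
    for (f in c("attP", "attB")) {
      add(paste0("inh:", f), c(paste0(f, "_int"), "int2"), paste0(f, "_T"),
          kf[["kf_inh"]], kf[["kf_inh"]] / K[["K_inh"]])
    }
  }
  # bimolecular synapsis of bound fragments; K_s1 in 1/nM
  add("s1", c("attP_int", "attB_int"), "PB_s",
      kf[["kf_s1"]], kf[["kf_s1"]] / K[["K_s1"]])
  add("r1", "PB_s", "LR_s1", kf[["kf_r1"]], kf[["kf_r1"]] / K[["K_r1"]])
  add("mod", "LR_s1", "LR_s2", kf[["kf_mod"]], kf[["kf_mod"]] / K[["K_mod"]])
  # desynapsis releases two separate bound product fragments; K_s2 in nM
  add("s2", "LR_s2", c("attL_int", "attR_int"),
      kf[["kf_s2"]], kf[["kf_s2"]] / K[["K_s2"]])

  .assemble_network(params, species, steps,
                    substrates = c(linear_PB = "linear"))
}

# -- assembly ------------------------------------------------------------

.assemble_network <- function(params, species, steps, substrates) {
  sp_names <- species$name
  n <- length(sp_names)
  m <- length(steps)
  idx <- function(x) match(x, sp_names)
  pad <- n + 1L  # dummy index: concentration fixed at 1

  ridx <- matrix(pad, m, 2); pidx <- matrix(pad, m, 2)
  S <- matrix(0, n, m, dimnames = list(sp_names, NULL))
  kfv <- numeric(m); krv <- numeric(m); nms <- character(m)
  for (k in seq_len(m)) {
    st <- steps[[k]]
    ri <- idx(st$r); pi <- idx(st$p)
    if (anyNA(c(ri, pi))) stop("unknown species in step ", st$name)
    ridx[k, seq_along(ri)] <- ri
    pidx[k, seq_along(pi)] <- pi
    for (i in ri) S[i, k] <- S[i, k] - 1
    for (i in pi) S[i, k] <- S[i, k] + 1
    kfv[k] <- st$kf; krv[k] <- st$kr
    nms[k] <- st$name
  }
  colnames(S) <- nms
  if (any(kfv <= 0) || any(krv <= 0)) {
    stop("all steps must be reversible with positive rates")
  }

  cons <- rbind(DNA = .dna_weights(species),
                integrase = species$n_int,
                RDF = species$n_rdf)
  colnames(cons) <- sp_names
  if (identical(unname(substrates), "linear")) {
    # linear fragments: attP-equivalents, attB-equivalents and the L/R
    # pairing balance are conserved separately
    half <- .linear_half_weights(species)
    cons <- rbind(attP_equiv = half$P, attB_equiv = half$B,
                  integrase = species$n_int, LR_balance = half$bal)
    colnames(cons) <- sp_names
  }

  structure(list(variant = params$variant, params = params,
                 species = species, step_names = nms,
                 ridx = ridx, pidx = pidx, kf = kfv, kr = krv,
                 stoich = S, conservation = cons,
                 substrates = substrates),
            class = "rec_network")
}

.dna_weights <- function(species) as.numeric(species$n_dna)

.linear_half_weights <- function(species) {
  cfg <- species$config
  P <- ifelse(is.na(cfg), 0,
              ifelse(cfg %in% c("P", "S", "SL"), 1,
                     ifelse(cfg %in% c("L", "R"), 0.5, 0)))
  B <- ifelse(is.na(cfg), 0,
              ifelse(cfg %in% c("B", "S", "SL"), 1,
                     ifelse(cfg %in% c("L", "R"), 0.5, 0)))
  bal <- ifelse(is.na(cfg), 0, ifelse(cfg == "L", 1, ifelse(cfg == "R", -1, 0)))
  list(P = P, B = B, bal = bal)
}

setdiff2 <- function(x, drop) {
  # remove ONE occurrence of `drop` from x (setdiff would remove all)
  i <- match(drop, x)
  if (is.na(i)) x else x[-i]
}

#' @export
print.rec_network <- function(x, ...) {
  cat("<rec_network>", x$variant, "-", nrow(x$species), "species,",
      length(x$step_names), "reversible steps\n")
  cat("  conservation laws:", paste(rownames(x$conservation), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tabulate the steps of a network
#'
#' Human-readable step table (one row per reversible step) for
#' cross-checking the assembled network: reactants, products, forward and
#' reverse rate constants and the implied equilibrium constant.
#'
#' @param network a \code{rec_network}.
#' @return a data frame with columns \code{step}, \code{reactants},
#'   \code{products}, \code{kf}, \code{kr}, \code{K}.
#' @export
network_steps <- function(network) {
  stopifnot(inherits(network, "rec_network"))
  n <- nrow(network$species)
  nm <- c(network$species$name, "")
  side <- function(ix) apply(ix, 1, function(r)
    paste(nm[r[r <= n]], collapse = " + "))
  data.frame(step = network$step_names,
             reactants = side(network$ridx),
             products = side(network$pidx),
             kf = network$kf, kr = network$kr,
             K = network$kf / network$kr,
             row.names = NULL)
}

# -- initial state and RHS ----------------------------------------------

#' Initial species state for a simulation
#'
#' All protein is initially free monomer and all DNA unbound; solution
#' complexation (integrase dimerization, RDF loading) then evolves
#' kinetically, which is fast on the timescale of DNA binding at the
#' concentrations modelled.
#'
#' @param network a \code{rec_network}.
#' @param substrate \code{"pPB"}, \code{"pLR"} (plasmid variants) or
#'   \code{"linear_PB"} (linear variant).
#' @param dna_nM DNA concentration: per plasmid, or per fragment for the
#'   linear substrate (attP and attB each at \code{dna_nM}).
#' @param int_nM total integrase, as monomer.
#' @param rdf_nM total RDF, as monomer. Must be 0 for the linear variant.
#' @return named numeric vector of concentrations (nM) over the network
#'   species.
#' @export
initial_state <- function(network, substrate, dna_nM, int_nM, rdf_nM = 0) {
  stopifnot(inherits(network, "rec_network"))
  if (dna_nM < 0 || int_nM < 0 || rdf_nM < 0) {
    stop("concentrations must be non-negative")
  }
  if (!substrate %in% names(network$substrates)) {
    stop("substrate ", substrate, " not available for ", network$variant,
         " (choose from: ", paste(names(network$substrates), collapse = ", "),
         ")")
  }
  y <- stats::setNames(numeric(nrow(network$species)), network$species$name)
  y["int"] <- int_nM
  if (network$variant == "MODEL1_LINEAR") {
    if (rdf_nM > 0) stop("the linear variant models the -RDF pathway only")
    y["attP"] <- dna_nM
    y["attB"] <- dna_nM
  } else {
    y["rdf"] <- rdf_nM
    y[network$substrates[[substrate]]] <- dna_nM
  }
  attr(y, "substrate") <- substrate
  y
}

#' Mass-action time derivatives
#'
#' Pure mass-action right-hand side of the network ODE system: each step
#' contributes \code{kf * prod(reactants) - kr * prod(products)} with
#' stoichiometric signs. The derivative of every conservation total is zero
#' to machine precision by construction.
#'
#' @param state named concentration vector (nM) covering every species.
#' @param network a \code{rec_network}.
#' @return named vector of time derivatives (nM/s).
#' @export
rhs <- function(state, network) {
  stopifnot(inherits(network, "rec_network"))
  y <- state[network$species$name]
  if (anyNA(y)) stop("state does not cover every network species")
  if (any(y < -1e-9)) stop("negative concentration in state")
  stats::setNames(.rhs_raw(pmax(y, 0), network), network$species$name)
}

.rhs_raw <- function(y, network) {
  yp <- c(y, 1)
  v <- network$kf * yp[network$ridx[, 1]] * yp[network$ridx[, 2]] -
       network$kr * yp[network$pidx[, 1]] * yp[network$pidx[, 2]]
  drop(network$stoich %*% v)
}

.step_fluxes <- function(y, network) {
  yp <- c(y, 1)
  stats::setNames(
    network$kf * yp[network$ridx[, 1]] * yp[network$ridx[, 2]] -
      network$kr * yp[network$pidx[, 1]] * yp[network$pidx[, 2]],
    network$step_names)
}

# analytic Jacobian of .rhs_raw (also used by the stiff integrator)
.jac_raw <- function(y, network) {
  n <- length(y)
  m <- length(network$kf)
  yp <- c(y, 1)
  dv <- matrix(0, m, n + 1)
  i1 <- cbind(seq_len(m), network$ridx[, 1])
  dv[i1] <- dv[i1] + network$kf * yp[network$ridx[, 2]]
  i2 <- cbind(seq_len(m), network$ridx[, 2])
  dv[i2] <- dv[i2] + network$kf * yp[network$ridx[, 1]]
  j1 <- cbind(seq_len(m), network$pidx[, 1])
  dv[j1] <- dv[j1] - network$kr * yp[network$pidx[, 2]]
  j2 <- cbind(seq_len(m), network$pidx[, 2])
  dv[j2] <- dv[j2] - network$kr * yp[network$pidx[, 1]]
  network$stoich %*% dv[, seq_len(n), drop = FALSE]
}

#' Conservation totals of a state
#'
#' @param state named concentration vector.
#' @param network a \code{rec_network}.
#' @return named numeric vector, one entry per conservation law.
#' @export
conservation_totals <- function(state, network) {
  stopifnot(inherits(network, "rec_network"))
  drop(network$conservation %*% state[network$species$name])
}
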