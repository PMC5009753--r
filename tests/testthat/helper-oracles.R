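# Independent equilibrium oracle for -RDF plasmid conditions.
#
# At equilibrium a detailed-balanced network is a grand-canonical
# statistical-mechanics problem: every DNA species' concentration is the
# free-plasmid concentration times a product of per-step equilibrium
# constants and statistical factors along any path from free DNA. With no
# RDF present the unknowns reduce to the free integrase monomer m and the
# free substrate plasmid p, fixed by the two conservation equations. This
# derivation shares no code with the ODE right-hand side or the Newton
# polish, so agreement between the two routes is a genuine cross-check.
oracle_equilibrium_noRDF <- function(params, dna_nM, int_nM) {
  K <- params$K
  model1 <- params$variant == "MODEL1_PLASMID"
  weights <- function(m) {
    d <- m^2 / K[["K_ii"]]               # free integrase dimer
    b1 <- K[["K_b1"]] * d                # per-site occupancy, attP/attB
    b2 <- K[["K_b2"]] * d                # per-site occupancy, attL/attR
    ti <- if (params$tetramer_inhibition) K[["K_inh"]] * d else 0
    path <- K[["K_s1"]] * K[["K_r1"]] *
      (if (model1) K[["K_mod"]] * K[["K_s2"]] else K[["K_s2"]])
    wLRint <- b1^2 * path                # equals b2^2 for a closed set
    w <- c(
      PB = 1, PB_int1 = 2 * b1, PB_int = b1^2,
      PB_int_s = b1^2 * K[["K_s1"]],
      LR_int_s1 = b1^2 * K[["K_s1"]] * K[["K_r1"]],
      LR_int = wLRint,
      LR_int1 = 2 * wLRint / b2,
      LR = wLRint / b2^2)
    if (model1) {
      w["LR_int_s2"] <- b1^2 * K[["K_s1"]] * K[["K_r1"]] * K[["K_mod"]]
    }
    if (params$tetramer_inhibition) {
      w["PB_E.T"] <- 2 * b1 * ti
      w["PB_I.T"] <- 2 * b1 * (b1 * ti)
      w["PB_T.T"] <- (b1 * ti)^2
    }
    w
  }
  n_int <- function(nm) {
    c(PB = 0, PB_int1 = 2, PB_int = 4, PB_int_s = 4, LR_int_s1 = 4,
      LR_int_s2 = 4, LR_int = 4, LR_int1 = 2, LR = 0,
      PB_E.T = 4, PB_I.T = 6, PB_T.T = 8)[nm]
  }
  int_balance <- function(m) {
    w <- weights(m)
    p <- dna_nM / sum(w)
    m + 2 * m^2 / K[["K_ii"]] + p * sum(w * n_int(names(w))) - int_nM
  }
  m <- stats::uniroot(int_balance, c(1e-12, int_nM), tol = 1e-14)$root
  w <- weights(m)
  p <- dna_nM / sum(w)
  state <- c(int = m, int2 = m^2 / K[["K_ii"]], stats::setNames(p * w, names(w)))
  list(state = state,
       fraction_LR = sum(state[grep("^LR", names(state))]) / dna_nM)
}
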