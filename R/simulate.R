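# Time-course integration, recombinant-fraction readouts, equilibria.
#
# The networks are stiff: second-scale protein binding coexists with
# desynapsis steps whose characteristic times are days. Integration uses
# deSolve's lsoda (switching BDF) with the analytic Jacobian, rtol 1e-8 and
# atol 1e-12 nM by default. Requested output times are honoured exactly by
# the integrator's dense output, so "30 min" readouts are interpolation
# points, not nearest samples.

.SOLVER_DEFAULTS <- list(rtol = 1e-8, atol = 1e-12)

#' Simulate a reaction network
#'
#' @param network a \code{rec_network}.
#' @param initial named initial concentration vector from
#'   [initial_state()].
#' @param times strictly increasing vector of output times (s), starting at
#'   or after 0.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method; default \code{"lsoda"}
#'   (automatic stiff/non-stiff switching). Long-horizon equilibrium runs
#'   use \code{"bdf"}.
#' @return an object of class \code{rec_sim}: list with \code{times},
#'   \code{conc} (time x species matrix, nM), \code{network},
#'   \code{substrate} and solver metadata. Concentrations are clipped at
#'   -1e-9 (hard error below), then floored at 0.
#' @export
simulate_network <- function(network, initial, times,
                             rtol = .SOLVER_DEFAULTS$rtol,
                             atol = .SOLVER_DEFAULTS$atol,
                             method = "lsoda") {
  stopifnot(inherits(network, "rec_network"))
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  y0 <- initial[network$species$name]
  if (anyNA(y0)) stop("initial state does not cover every network species")
  t_out <- if (times[1] > 0) c(0, times) else times

  # the RHS is evaluated without clipping: mass action is polynomial and
  # smooth through zero, and clipping would break the Jacobian consistency
  # the stiff solver relies on; tiny negative excursions (~atol) are
  # tolerated and floored in the returned trajectory
  func <- function(t, y, p) list(.rhs_raw(y, network))
  jac <- function(t, y, p) .jac_raw(y, network)
  out <- deSolve::ode(y = unname(y0), times = t_out, func = func,
                      parms = NULL, jacfunc = jac, jactype = "fullusr",
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 500000)
  if (attr(out, "istate")[1] < 0) {
    stop("integrator failed (istate = ", attr(out, "istate")[1], ") at t = ",
         max(out[, 1]))
  }
  conc <- out[match(times, out[, 1]), -1, drop = FALSE]
  if (any(conc < -1e-9)) {
    stop("negative concentrations beyond solver slack; tighten tolerances")
  }
  conc[conc < 0] <- 0
  colnames(conc) <- network$species$name
  structure(list(times = times, conc = conc, network = network,
                 substrate = attr(initial, "substrate"),
                 initial = y0, rtol = rtol, atol = atol),
            class = "rec_sim")
}

#' @export
print.rec_sim <- function(x, ...) {
  cat("<rec_sim>", x$network$variant, "-", length(x$times), "time points,",
      ncol(x$conc), "species\n")
  invisible(x)
}

#' Fraction of DNA in the recombinant configuration
#'
#' Mirrors the experimental readout (deproteinized, digested DNA): every
#' species whose DNA is in the recombinant configuration counts, including
#' synaptic complexes. For a \code{pPB} start the recombinant fraction is
#' all LR-configuration species over total plasmid; symmetric for
#' \code{pLR}. For the linear substrate the readout is attL-containing DNA
#' relative to the total amount of attB (synapses count once; free/bound
#' attL and attR count half each, being one recombinant junction of the
#' pair).
#'
#' @param sim a \code{rec_sim}.
#' @param substrate substrate identity; defaults to the one recorded in the
#'   simulation.
#' @return numeric vector in [0, 1], one value per time point.
#' @export
fraction_recombinant <- function(sim, substrate = sim$substrate) {
  stopifnot(inherits(sim, "rec_sim"))
  .fraction_from_conc(sim$conc, sim$network, substrate)
}

.fraction_from_conc <- function(conc, network, substrate) {
  sp <- network$species
  if (network$variant == "MODEL1_LINEAR") {
    w <- ifelse(is.na(sp$config), 0,
                ifelse(sp$config == "SL", 1,
                       ifelse(sp$config %in% c("L", "R"), 0.5, 0)))
    tot <- drop(conc %*% network$conservation["attB_equiv", ])
    num <- drop(conc %*% w)
  } else {
    if (!substrate %in% c("pPB", "pLR")) stop("unknown substrate ", substrate)
    rec_cfg <- if (substrate == "pPB") "LR" else "PB"
    w <- as.numeric(!is.na(sp$config) & sp$config == rec_cfg)
    tot <- drop(conc %*% as.numeric(!is.na(sp$config)))
    num <- drop(conc %*% w)
  }
  if (any(tot <= 0)) stop("zero total DNA: recombinant fraction undefined")
  unname(pmin(pmax(num / tot, 0), 1))
}

# -- equilibrium ---------------------------------------------------------

#' Equilibrium composition of a network
#'
#' Finds the steady state by long-horizon integration (default 1e8 s,
#' beyond the slowest desynapsis relaxation) followed by a Gauss--Newton
#' polish of \code{rhs = 0} under the conservation constraints, performed in
#' log-concentration space on the species populated by the trajectory.
#' The polished state is verified: residual derivatives below \code{tol_rhs}
#' and, for these detailed-balanced networks, near-zero net flux through
#' every individual step.
#'
#' Because the networks satisfy detailed balance, the equilibrium reached is
#' independent of whether the system starts from substrate or product DNA
#' with the same totals: only the 3-h snapshots differ, which is the
#' kinetic-trapping phenomenon the models exist to describe.
#'
#' @param network a \code{rec_network} (closed parameters).
#' @param initial initial state from [initial_state()].
#' @param t_horizon integration horizon (s).
#' @param tol_rhs acceptance threshold on \code{max |d[x]/dt|} (nM/s).
#' @return list with \code{state} (named concentrations, nM),
#'   \code{fraction_recombinant}, \code{max_rhs}, \code{max_step_flux} and
#'   \code{conservation} totals.
#' @export
equilibrium_composition <- function(network, initial, t_horizon = 1e8,
                                    tol_rhs = 1e-10) {
  stopifnot(inherits(network, "rec_network"))
  sim <- simulate_network(network, initial,
                          times = 10^seq(0, log10(t_horizon), length.out = 9),
                          method = "bdf")
  y <- sim$conc[nrow(sim$conc), ]
  y <- .newton_polish(y, network)
  r <- .rhs_raw(y, network)
  if (max(abs(r)) > tol_rhs) {
    stop("equilibrium polish did not converge: max |rhs| = ",
         signif(max(abs(r)), 3), " nM/s")
  }
  cons0 <- conservation_totals(initial[network$species$name], network)
  structure(list(
    state = stats::setNames(y, network$species$name),
    fraction_recombinant = .fraction_from_conc(rbind(y), network,
                                               attr(initial, "substrate")),
    max_rhs = max(abs(r)),
    max_step_flux = max(abs(.step_fluxes(y, network))),
    conservation = cons0,
    substrate = attr(initial, "substrate")),
    class = "rec_equilibrium")
}

#' @export
print.rec_equilibrium <- function(x, ...) {
  cat(sprintf("<rec_equilibrium> fraction recombinant %.4f (max |rhs| %.2e, max |step flux| %.2e)\n",
              x$fraction_recombinant, x$max_rhs, x$max_step_flux))
  invisible(x)
}

# Gauss-Newton on log concentrations of the active species, with the
# conservation laws appended as equations (scaled by their totals).
.newton_polish <- function(y, network, max_iter = 60) {
  n <- length(y)
  active <- y > 1e-25
  cons <- network$conservation
  b <- drop(cons %*% y)
  A <- cons[, active, drop = FALSE]
  bs <- pmax(abs(b), 1)  # zero-total laws (e.g. attL/attR balance) kept
  x <- log(y[active])
  obj <- function(x) {
    yy <- y
    yy[active] <- exp(x)
    r <- .rhs_raw(yy, network)
    c(r, (drop(A %*% exp(x)) - b) / bs)
  }
  best <- x
  best_norm <- Inf
  for (it in seq_len(max_iter)) {
    yy <- y
    yy[active] <- exp(x)
    J <- .jac_raw(yy, network)[, active, drop = FALSE] *
      rep(exp(x), each = n)
    Jc <- A * rep(exp(x), each = nrow(A)) / bs
    Jfull <- rbind(J, Jc)
    f <- obj(x)
    # row equilibration: flux magnitudes span many orders between fast
    # binding steps and day-scale desynapsis
    rs <- pmax(apply(abs(Jfull), 1, max), 1e-300)
    nrm <- function(v) sqrt(sum((v / rs)^2))
    if (nrm(f) < best_norm) {
      best <- x
      best_norm <- nrm(f)
    }
    if (best_norm < 1e-15) break
    dx <- tryCatch(qr.solve(Jfull / rs, -f / rs), error = function(e) NULL)
    if (is.null(dx)) break
    dx <- pmax(pmin(dx, 2), -2)
    step <- 1
    repeat {
      xn <- x + step * dx
      fn <- obj(xn)
      if (nrm(fn) < nrm(f) || step < 1e-4) break
      step <- step / 2
    }
    x <- xn
  }
  y[active] <- exp(best)
  y
}

# -- concentration scans -------------------------------------------------

#' Endpoint recombination over a grid of protein concentrations
#'
#' Runs one simulation per grid point and reports the recombinant fraction
#' at time \code{t_h} (default 3 h), the design of the endpoint titration
#' experiments.
#'
#' @param network a \code{rec_network}.
#' @param substrate substrate identity.
#' @param int_grid integrase concentrations (nM monomer).
#' @param rdf_grid RDF concentrations (nM monomer); crossed with
#'   \code{int_grid}.
#' @param dna_nM substrate DNA concentration (default 10 nM).
#' @param t_h endpoint time in hours.
#' @return a data frame (\code{scan_table}) with columns \code{int_nM},
#'   \code{rdf_nM}, \code{substrate}, \code{time_h},
#'   \code{fraction_recombinant} and \code{status}; solver failures are
#'   flagged per row and do not abort the scan.
#' @export
concentration_scan <- function(network, substrate, int_grid, rdf_grid = 0,
                               dna_nM = 10, t_h = 3) {
  stopifnot(inherits(network, "rec_network"))
  if (any(int_grid < 0) || any(rdf_grid < 0)) stop("grids must be non-negative")
  grid <- expand.grid(int_nM = int_grid, rdf_nM = rdf_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    fr <- tryCatch({
      y0 <- initial_state(network, substrate, dna_nM,
                          grid$int_nM[i], grid$rdf_nM[i])
      sim <- simulate_network(network, y0, times = t_h * 3600)
      fraction_recombinant(sim)
    }, error = function(e) NA_real_)
    data.frame(int_nM = grid$int_nM[i], rdf_nM = grid$rdf_nM[i],
               substrate = substrate, time_h = t_h,
               fraction_recombinant = fr,
               status = if (is.na(fr)) "failed" else "ok")
  })
  structure(do.call(rbind, out), class = c("scan_table", "data.frame"))
}
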