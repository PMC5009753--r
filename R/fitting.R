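# Model-data agreement, constrained parameter estimation, robustness.
#
# The published calibration was manual; this module provides the
# reproducible automated counterpart: a least-squares objective over an
# experiment-shaped dataset, local constrained fitting in log-parameter
# space (optionally multi-start), with Wegscheider closure re-imposed at
# every objective evaluation so no candidate ever violates energy
# conservation.

#' Sum-of-squares objective
#'
#' Residuals are simulated minus observed recombinant fractions over the
#' dataset rows. Unweighted by default; with \code{weighted = TRUE}
#' residuals are scaled by 1/sd (rows with sd = 0 fall back to the median
#' positive sd). The parameter set is verified closed before any
#' simulation.
#'
#' @param params a closed \code{rec_params}.
#' @param dataset an \code{experiment_dataset} (or compatible data frame).
#' @param weighted logical; 1/sd^2 weighting.
#' @return scalar objective (>= 0). The residual vector is attached as
#'   attribute \code{"residuals"}.
#' @export
objective <- function(params, dataset, weighted = FALSE) {
  res <- wegscheider_residuals(params)
  if (any(res > 1e-9)) stop("objective requires a closed parameter set")
  pred <- predict_design(params, dataset)
  r <- pred - dataset$fraction_recombinant
  if (weighted) {
    s <- dataset$sd
    s[s <= 0] <- stats::median(s[s > 0])
    if (anyNA(s)) s[] <- 1
    r <- r / s
  }
  structure(sum(r^2), residuals = r)
}

#' Fit parameters to a dataset
#'
#' Local constrained least squares (Levenberg--Marquardt via
#' \pkg{minpack.lm}) in log-parameter space from \code{init_params},
#' optionally multi-start with log-uniform jitter. The closure-derived
#' constants (\code{K_s2}, \code{K_s4}) are excluded from the free set and
#' recomputed at every evaluation, so every candidate -- intermediate or
#' final -- conserves energy.
#'
#' Default bounds: association rate constants 1e-6 to 1 1/(nM s) (1e3 to
#' 1e9 1/(M s), the typically observed range for protein-DNA and
#' protein-protein association), all other constants within 1e4-fold of the
#' initial value.
#'
#' @param dataset an \code{experiment_dataset}.
#' @param init_params starting \code{rec_params} (closed).
#' @param free_names constants to fit (names in \code{K}/\code{kf}); must
#'   exclude the derived constants.
#' @param bounds optional named list of \code{c(lower, upper)} per free
#'   constant (natural scale).
#' @param n_starts multi-start count (1 = single local fit).
#' @param seed RNG seed for multi-start jitter.
#' @param weighted passed to [objective()].
#' @return a \code{fit_result}: list with \code{params} (closed fitted set),
#'   \code{objective}, \code{residuals}, \code{free_names},
#'   \code{at_bounds} flags, and a per-start \code{trace}.
#' @export
fit_parameters <- function(dataset, init_params, free_names,
                           bounds = NULL, n_starts = 1, seed = 1,
                           weighted = FALSE) {
  stopifnot(inherits(init_params, "rec_params"))
  derived <- c("K_s2", "K_s4")
  if (any(free_names %in% derived)) {
    stop("closure-derived constants (", paste(derived, collapse = ", "),
         ") cannot be in the free set")
  }
  all_names <- c(names(init_params$K), names(init_params$kf))
  if (!all(free_names %in% all_names)) {
    stop("unknown constants: ",
         paste(setdiff(free_names, all_names), collapse = ", "))
  }

  theta0 <- log(.get_constants(init_params, free_names))
  lo <- up <- stats::setNames(numeric(length(free_names)), free_names)
  for (nm in free_names) {
    if (!is.null(bounds[[nm]])) {
      lo[nm] <- log(bounds[[nm]][1]); up[nm] <- log(bounds[[nm]][2])
    } else if (grepl("^kf_(b|ii|ir|inh)", nm) ||
               (nm == "kf_s1" && init_params$variant == "MODEL1_LINEAR")) {
      lo[nm] <- log(1e-6); up[nm] <- log(1)  # bimolecular association
    } else {
      lo[nm] <- theta0[nm] - log(1e4); up[nm] <- theta0[nm] + log(1e4)
    }
  }
  if (any(lo >= up)) stop("infeasible bounds")
  theta0 <- pmin(pmax(theta0, lo), up)

  resid_fn <- function(theta) {
    p <- .set_free(init_params, free_names, exp(theta))
    p <- close_parameters(p)
    attr(objective(p, dataset, weighted = weighted), "residuals")
  }

  set.seed(as.integer(seed))
  starts <- list(theta0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- pmin(pmax(
        theta0 + stats::runif(length(theta0), -log(3), log(3)), lo), up)
    }
  }
  trace <- list()
  best <- NULL
  for (s in seq_along(starts)) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], lower = lo, upper = up,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                           # forward-difference step ~1e-3 on log-parameters:
                           # safely above the ODE solver noise floor
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(ans)) {
      trace[[s]] <- list(start = s, status = "failed")
      next
    }
    ssr <- sum(ans$fvec^2)
    trace[[s]] <- list(start = s, status = "ok", objective = ssr,
                       iterations = ans$niter, message = ans$message)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = ans, ssr = ssr)
  }
  if (is.null(best)) stop("all optimizer starts failed")

  theta <- best$fit$par
  fitted <- close_parameters(.set_free(init_params, free_names, exp(theta)))
  at_bounds <- (theta <= lo + 1e-8) | (theta >= up - 1e-8)
  structure(list(params = fitted, objective = best$ssr,
                 residuals = best$fit$fvec,
                 free_names = free_names,
                 estimates = stats::setNames(exp(theta), free_names),
                 at_bounds = stats::setNames(at_bounds, free_names),
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", signif(x$objective, 6), "\n")
  print(signif(x$estimates, 4))
  if (any(x$at_bounds)) {
    cat("  at bounds:", paste(names(which(x$at_bounds)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

.get_constants <- function(params, names) {
  vals <- c(params$K, params$kf)
  vals[names]
}

.set_free <- function(params, names, values) {
  p <- params
  for (i in seq_along(names)) {
    nm <- names[i]
    if (nm %in% names(p$K)) p$K[[nm]] <- values[i] else p$kf[[nm]] <- values[i]
  }
  p
}

# -- robustness ----------------------------------------------------------

#' Parameter-robustness scan of maximal product yields
#'
#' Multiplies each free parameter in turn by \code{fold} and by
#' \code{1/fold}, restores energy conservation (default) by recomputing the
#' closure-derived constants, simulates the two permitted reactions
#' (pPB with 400 nM integrase; pLR with 400 nM integrase + 800 nM RDF, both
#' at 10 nM plasmid), and reports the relative change in the maximal
#' product fraction over the time course against the unperturbed baseline.
#'
#' @param params a closed \code{rec_params} (plasmid variant).
#' @param fold perturbation factor (default 2).
#' @param parameters constants to scan; default all free constants (every
#'   K except the closure-derived K_s2/K_s4, and every forward rate).
#' @param reclose if \code{TRUE} (default) perturbed sets are re-closed via
#'   K_s2/K_s4; if \code{FALSE} the perturbation is applied directly and
#'   the network is built in diagnostic (unclosed) mode.
#' @param t_max_h time-course horizon for "maximal yield" (hours).
#' @param int_nM,rdf_nM,dna_nM reaction conditions.
#' @return data frame with one row per (parameter, direction, reaction):
#'   columns \code{parameter}, \code{fold}, \code{reaction},
#'   \code{max_yield}, \code{baseline}, \code{rel_change}, \code{status}.
#' @export
robustness_scan <- function(params, fold = 2, parameters = NULL,
                            reclose = TRUE, t_max_h = 3,
                            int_nM = 400, rdf_nM = 800, dna_nM = 10) {
  stopifnot(inherits(params, "rec_params"))
  if (is.null(parameters)) {
    parameters <- setdiff(c(names(params$K), names(params$kf)),
                          c("K_s2", "K_s4"))
  }
  times <- seq(60, t_max_h * 3600, by = 60)
  max_yield <- function(p) {
    net <- build_network(p$variant, p, allow_unclosed = !reclose)
    vapply(list(
      PxB = initial_state(net, "pPB", dna_nM, int_nM, 0),
      LxR = initial_state(net, "pLR", dna_nM, int_nM, rdf_nM)),
      function(y0) max(fraction_recombinant(simulate_network(net, y0, times))),
      numeric(1))
  }
  base <- max_yield(params)
  folds <- unique(c(fold, 1 / fold))
  rows <- list()
  for (nm in parameters) for (f in folds) {
    yy <- tryCatch({
      p2 <- .set_free(params, nm, .get_constants(params, nm) * f)
      if (reclose) p2 <- close_parameters(p2)
      max_yield(p2)
    }, error = function(e) c(PxB = NA_real_, LxR = NA_real_))
    rows[[length(rows) + 1]] <- data.frame(
      parameter = nm, fold = f, reaction = names(base),
      max_yield = unname(yy), baseline = unname(base),
      rel_change = unname((yy - base) / base),
      status = ifelse(is.na(yy), "failed", "ok"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
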