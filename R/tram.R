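# Assemble estimator inputs from a count model: stacked TRAM-set and
# MBAR-set samples with state, ensemble and K bias energies each.
memm_data <- function(cm) {
  stopifnot(inherits(cm, "count_model"))
  K <- cm$n_ensembles
  ts <- te <- ms <- me <- integer(0)
  tb <- mb <- NULL
  tbl <- list(); mbl <- list()
  for (tr in cm$trajs) {
    b <- tr$bias
    if (is.null(b)) b <- matrix(0.0, length(tr$states), K)
    if (ncol(b) != K) stop("bias matrices must have one column per ensemble")
    if (tr$role == "mbar") {
      ms <- c(ms, tr$states); me <- c(me, rep(tr$ensemble, length(tr$states)))
      mbl[[length(mbl) + 1L]] <- b
    } else {
      ts <- c(ts, tr$states); te <- c(te, rep(tr$ensemble, length(tr$states)))
      tbl[[length(tbl) + 1L]] <- b
    }
  }
  tb <- if (length(tbl)) do.call(rbind, tbl) else matrix(0.0, 0, K)
  mb <- if (length(mbl)) do.call(rbind, mbl) else matrix(0.0, 0, K)
  list(tram_state = ts, tram_ens = te, tram_bias = tb,
       mbar_state = ms, mbar_ens = me, mbar_bias = mb)
}

memm_fit <- function(cm, dat, tol, max_iter, keep_trace) {
  n <- cm$n_states
  K <- cm$n_ensembles
  res <- .tram_core_cpp(cm$counts,
                        dat$tram_state - 1L, dat$tram_ens, dat$tram_bias,
                        dat$mbar_state - 1L, dat$mbar_ens, dat$mbar_bias,
                        tol, as.integer(max_iter), keep_trace)
  p <- lapply(seq_len(K), function(k) res$transition_arr[, , k])
  pi0 <- exp(-res$f_ik[, 1])
  pi0 <- pi0 / sum(pi0)
  conv <- list(iterations = res$iterations,
               max_free_energy_increment = res$max_increment,
               log_likelihood = res$log_likelihood,
               log_likelihood_trace = res$log_likelihood_trace,
               converged = res$converged)
  if (!res$converged)
    warning(sprintf(
      "estimator not converged after %d iterations (increment %.3g)",
      res$iterations, res$max_increment))
  structure(list(
    state_ensemble_free_energies = res$f_ik,
    ensemble_free_energies = res$f_k,
    log_nu = res$log_nu,
    point_weights = list(
      log_mu_tram = res$log_mu_tram, log_mu_mbar = res$log_mu_mbar,
      tram_state = dat$tram_state, tram_ens = dat$tram_ens,
      mbar_state = dat$mbar_state, mbar_ens = dat$mbar_ens),
    transition_matrices = p,
    unbiased_stationary = pi0,
    convergence = conv,
    n_states = n, n_ensembles = K,
    active = cm$active, lag = cm$lag, counts = cm$counts),
    class = "memm_result")
}

#' TRAM estimator for multi-ensemble Markov models
#'
#' Maximizes the transition-based reweighting (TRAM) likelihood
#' \deqn{L = \prod_{k,i,j} (p_{ij}^k)^{c_{ij}^k} \prod_{x \in X^k \cap S_i}
#'   \mu(x) e^{f_i^k - b^k(x)}}
#' over row-stochastic transition matrices \eqn{p^k} reversible with respect
#' to \eqn{e^{-f_i^k}}, joint state-ensemble free energies \eqn{f_i^k} and
#' point weights \eqn{\mu(x)}, by the self-consistent fixed-point iteration in
#' log space. MBAR-set trajectories present in the count model are ignored;
#' use [trammbar_estimate()] to include equilibrium data.
#'
#' @param cm a \code{count_model}, typically after [apply_connectivity()];
#'   every active state must carry at least one sample.
#' @param tol convergence threshold on the sup-norm free-energy increment
#'   (the log-likelihood must additionally be stable to 1e-8).
#' @param max_iter iteration cap; non-convergence is flagged with a warning.
#' @param trace keep the per-iteration log-likelihood trace (slower).
#' @return a \code{memm_result}; see [trammbar_estimate()].
#' @export
tram_estimate <- function(cm, tol = 1e-10, max_iter = 100000, trace = TRUE) {
  dat <- memm_data(cm)
  if (length(dat$tram_state) == 0)
    stop("no TRAM-set samples; use mbar_estimate/trammbar_estimate for ",
         "pure equilibrium data")
  dat$mbar_state <- integer(0)
  dat$mbar_ens <- integer(0)
  dat$mbar_bias <- matrix(0.0, 0, cm$n_ensembles)
  memm_fit(cm, dat, tol, max_iter, keep_trace = trace)
}

#' TRAMMBAR estimator: TRAM with additional equilibrium data
#'
#' Maximizes the product likelihood \eqn{L_{TRAM} \cdot L_{MBAR}}:
#' time-correlated (TRAM-set) trajectories contribute transition counts and
#' local-equilibrium terms, while equilibrium (MBAR-set) samples enter
#' through the standard MBAR likelihood with ensemble free energies coupled
#' to the state level by \eqn{e^{-f^k} = \sum_i e^{-f_i^k}}. With an empty
#' equilibrium set the result equals [tram_estimate()]; with no counts and no
#' TRAM-set samples the ensemble free energies equal [mbar_estimate()].
#'
#' @param cm a \code{count_model} (its MBAR-role trajectories are used as
#'   equilibrium data).
#' @param equilibrium_data optional additional list of
#'   \code{discrete_trajectory} objects with role \code{"mbar"}, carrying
#'   state assignments and bias matrices.
#' @param tol,max_iter as in [tram_estimate()].
#' @param trace keep the per-iteration log-likelihood trace (slower).
#' @return an object of class \code{memm_result} with components
#'   \describe{
#'     \item{state_ensemble_free_energies}{matrix \eqn{f_i^k} (states x
#'       ensembles), gauge \eqn{f^0 = 0}.}
#'     \item{ensemble_free_energies}{\eqn{f^k = -\log\sum_i e^{-f_i^k}}.}
#'     \item{point_weights}{log point weights \eqn{\mu(x)} and sample
#'       bookkeeping; \eqn{\sum_x \mu(x) = 1}.}
#'     \item{transition_matrices}{list of per-ensemble reversible
#'       row-stochastic matrices (rows \code{NA} where an ensemble has no
#'       counts).}
#'     \item{unbiased_stationary}{\eqn{\pi_i \propto e^{-f_i^0}}.}
#'     \item{convergence}{iteration count, final increment, log-likelihood
#'       trace, converged flag.}
#'   }
#' @export
trammbar_estimate <- function(cm, equilibrium_data = NULL, tol = 1e-10,
                              max_iter = 100000, trace = TRUE) {
  if (!is.null(equilibrium_data)) {
    if (inherits(equilibrium_data, "discrete_trajectory"))
      equilibrium_data <- list(equilibrium_data)
    for (tr in equilibrium_data)
      if (tr$role != "mbar")
        stop("equilibrium_data must have role 'mbar'")
    cm$trajs <- c(cm$trajs, equilibrium_data)
  }
  dat <- memm_data(cm)
  if (length(dat$tram_state) == 0 && length(dat$mbar_state) == 0)
    stop("no samples provided")
  memm_fit(cm, dat, tol, max_iter, keep_trace = trace)
}

#' Log-likelihood of a MEMM parameter set
#'
#' Evaluates the TRAMMBAR objective (the TRAM transition and sample terms
#' plus the MBAR equilibrium terms) at an arbitrary parameter point, e.g. a
#' random constraint-satisfying probe. Used to verify that the fixed-point
#' solution is the maximizer.
#'
#' @param cm the \code{count_model} that defines the data.
#' @param f_ik matrix of state-ensemble free energies (states x ensembles).
#' @param p list of per-ensemble transition matrices.
#' @param log_mu log point weights for the stacked samples, TRAM-set samples
#'   first then MBAR-set, in the order trajectories appear in \code{cm}.
#' @return scalar log-likelihood.
#' @export
trammbar_loglik <- function(cm, f_ik, p, log_mu) {
  dat <- memm_data(cm)
  K <- cm$n_ensembles
  ll <- 0
  for (k in seq_len(K)) {
    c_k <- cm$counts[, , k]
    nz <- which(c_k > 0, arr.ind = TRUE)
    if (nrow(nz))
      ll <- ll + sum(c_k[nz] * log(p[[k]][nz]))
  }
  nt <- length(dat$tram_state)
  if (nt) {
    lm <- log_mu[seq_len(nt)]
    ll <- ll + sum(lm + f_ik[cbind(dat$tram_state, dat$tram_ens + 1L)] -
                   dat$tram_bias[cbind(seq_len(nt), dat$tram_ens + 1L)])
  }
  nm <- length(dat$mbar_state)
  if (nm) {
    f_k <- vapply(seq_len(K), function(k) -logsumexp(-f_ik[, k]), numeric(1))
    lm <- log_mu[nt + seq_len(nm)]
    ll <- ll + sum(lm + f_k[dat$mbar_ens + 1L] -
                   dat$mbar_bias[cbind(seq_len(nm), dat$mbar_ens + 1L)])
  }
  ll
}

#' Unbiased stationary distribution of a MEMM
#'
#' @param m a converged \code{memm_result}.
#' @param use \code{"free-energies"} (\eqn{\pi_i \propto e^{-f_i^0}}, the
#'   default), \code{"samples-all"} (aggregate point weights of all samples
#'   per state) or \code{"samples-tram"} (TRAM-set samples only). At
#'   convergence \code{"samples-all"} coincides with the default; the
#'   TRAM-only aggregation answers how much the equilibrium data shifts the
#'   weight assignment.
#' @return probability vector over the active states (sums to 1).
#' @export
unbiased_stationary <- function(m, use = c("free-energies", "samples-all",
                                           "samples-tram")) {
  stopifnot(inherits(m, "memm_result"))
  use <- match.arg(use)
  if (use == "free-energies") {
    pi0 <- exp(-m$state_ensemble_free_energies[, 1])
    return(pi0 / sum(pi0))
  }
  pw <- m$point_weights
  st <- pw$tram_state
  lm <- pw$log_mu_tram
  if (use == "samples-all") {
    st <- c(st, pw$mbar_state)
    lm <- c(lm, pw$log_mu_mbar)
  }
  if (!length(st)) stop("no samples available for aggregation")
  pi0 <- vapply(seq_len(m$n_states), function(i) {
    v <- lm[st == i]
    if (length(v)) exp(logsumexp(v)) else 0
  }, numeric(1))
  pi0 / sum(pi0)
}

#' Dissociation constant from stationary populations
#'
#' \eqn{K_d = C_{box} \cdot \pi_{unbound} / \pi_{bound}} with the box
#' standard concentration \eqn{C_{box} = 1/(N_A V)} in mol/L, i.e. the
#' concentration of one free ligand in the simulation box.
#'
#' @param pi_bound,pi_unbound probabilities from the same normalized
#'   stationary distribution; \code{pi_bound} must be positive.
#' @param box_volume simulation box volume in nm^3.
#' @return dissociation constant in mol/L.
#' @export
kd_from_populations <- function(pi_bound, pi_unbound, box_volume) {
  stopifnot_scalar(pi_bound, "pi_bound")
  stopifnot_scalar(pi_unbound, "pi_unbound")
  if (pi_bound <= 0) stop("'pi_bound' must be positive")
  if (pi_unbound < 0) stop("'pi_unbound' must be non-negative")
  box_concentration(box_volume) * pi_unbound / pi_bound
}

#' Perturbative free-energy difference between two state sets
#'
#' Exponential-average (free energy perturbation) estimate of the effect of
#' a perturbation with per-sample unit-less energies \eqn{\Delta u(x)} on the
#' free-energy difference between state sets A and B:
#' \deqn{\Delta\Delta G = (G'_A - G_A) - (G'_B - G_B), \quad
#'   G'_S = -\ln \sum_{x \in S} \mu(x) e^{-\Delta u(x)}.}
#'
#' @param m a \code{memm_result}.
#' @param perturbation_energies numeric vector of \eqn{\Delta u} for the
#'   stacked samples (TRAM-set then MBAR-set, trajectory order).
#' @param state_set_A,state_set_B non-empty index sets of active states.
#' @return unit-less \eqn{\Delta\Delta G} (in \eqn{k_BT}).
#' @export
perturbative_ddg <- function(m, perturbation_energies, state_set_A,
                             state_set_B) {
  stopifnot(inherits(m, "memm_result"))
  if (!length(state_set_A) || !length(state_set_B))
    stop("state sets must be non-empty")
  pw <- m$point_weights
  st <- c(pw$tram_state, pw$mbar_state)
  lm <- c(pw$log_mu_tram, pw$log_mu_mbar)
  du <- as.numeric(perturbation_energies)
  if (length(du) != length(st))
    stop(sprintf("need one perturbation energy per sample (%d)", length(st)))
  g <- function(set, perturbed) {
    sel <- st %in% set
    if (!any(sel)) stop("state set holds no samples")
    v <- lm[sel]
    if (perturbed) v <- v - du[sel]
    -logsumexp(v)
  }
  (g(state_set_A, TRUE) - g(state_set_A, FALSE)) -
    (g(state_set_B, TRUE) - g(state_set_B, FALSE))
}

#' Extract the unbiased transition matrix of a MEMM
#'
#' Restricts ensemble \code{k}'s reversible transition matrix to the largest
#' set of states connected by counts in that ensemble, and attaches the
#' renormalized stationary distribution and the physical lag time.
#'
#' @param m a \code{memm_result}.
#' @param k 0-based ensemble index (default 0, the unbiased ensemble).
#' @param dt physical time per count frame (lag time = \code{m$lag * dt}).
#' @return a \code{transition_matrix} (see [transition_matrix()]) with an
#'   extra field \code{states}: indices into the MEMM's active set.
#' @export
extract_transition_matrix <- function(m, k = 0L, dt = 1) {
  stopifnot(inherits(m, "memm_result"))
  p <- m$transition_matrices[[k + 1L]]
  have <- which(!is.na(p[, 1]))
  if (!length(have)) stop("ensemble has no transition counts")
  cs <- m$counts[have, have, k + 1L]
  comp <- largest_component(cs + t(cs) > 0)
  sub <- have[comp]
  pi_sub <- exp(-m$state_ensemble_free_energies[sub, k + 1L])
  pi_sub <- pi_sub / sum(pi_sub)
  tm <- transition_matrix(p[sub, sub] / rowSums(p[sub, sub]),
                          lag = m$lag * dt, stationary = pi_sub)
  tm$states <- sub
  tm
}

#' @export
print.memm_result <- function(x, ...) {
  cat(sprintf("MEMM: %d states, %d ensembles, lag %d\n",
              x$n_states, x$n_ensembles, x$lag))
  cat(sprintf("  converged: %s after %d iterations (increment %.2e)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$max_free_energy_increment))
  cat(sprintf("  ensemble free energies: %s\n",
              paste(signif(x$ensemble_free_energies, 4), collapse = ", ")))
  invisible(x)
}
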