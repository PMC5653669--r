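#' Metropolis Monte Carlo sampling on a landscape
#'
#' Isotropic Gaussian displacement proposals of width \code{step_size},
#' accepted with probability \eqn{\min(1, e^{-\Delta U / k_BT})}. Proposals
#' into the excluded region are rejected. Sampling uses a dedicated counter
#' RNG seeded by \code{seed}, so identical seeds give bitwise-identical
#' trajectories regardless of R's RNG state.
#'
#' @param surface a \code{potential_surface} (possibly biased via
#'   [bias_surface()]).
#' @param start length-2 start coordinate; must be accessible.
#' @param n_steps number of MC steps (>= 1).
#' @param step_size proposal standard deviation; the default 0.12 gives an
#'   unbiased acceptance fraction near 0.5 inside the wells of the default
#'   landscape (higher on the flat plateau).
#' @param seed integer seed.
#' @param thin record every \code{thin}-th frame (frame 0 always recorded).
#' @return an \code{mc_trajectory} with fields \code{positions}
#'   (\code{(n_steps/thin + 1) x 2}), \code{ensemble_labels},
#'   \code{acceptance_fraction}, \code{step_size}, \code{seed}, \code{thin}.
#' @export
metropolis_sample <- function(surface, start, n_steps, step_size = 0.12,
                              seed = 1L, thin = 1L) {
  stopifnot(inherits(surface, "potential_surface"))
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  res <- .metropolis_cpp(unclass(surface), lambda_alpha(surface),
                         as.numeric(start), as.integer(n_steps),
                         step_size, as.numeric(seed), as.integer(thin))
  structure(list(positions = res$positions,
                 ensemble_labels = rep(0L, nrow(res$positions)),
                 acceptance_fraction = res$acceptance_fraction,
                 step_size = step_size, seed = seed, thin = as.integer(thin),
                 lambda = surface$lambda),
            class = "mc_trajectory")
}

#' Hamiltonian replica exchange across a bias schedule
#'
#' Runs one Metropolis walker per ensemble of the schedule and attempts
#' neighbor swaps every \code{exchange_interval} steps (alternating
#' even/odd pairs) with acceptance probability
#' \eqn{\min\{1, \exp[b^k(x_k) + b^l(x_l) - b^k(x_l) - b^l(x_k)]\}}.
#' Each returned trajectory carries its fixed ensemble label; coordinates
#' swap between ensembles. Swap decisions are drawn from a separate RNG
#' stream so that trajectory content at fixed swap outcomes does not depend
#' on bookkeeping order.
#'
#' @param surface unbiased \code{potential_surface}.
#' @param schedule a \code{bias_schedule} with K >= 2 ensembles.
#' @param n_steps steps per replica.
#' @param exchange_interval steps between exchange attempts (>= 1).
#' @param seed integer seed.
#' @param start optional K x 2 matrix of start coordinates; defaults to the
#'   bound-well center for every replica.
#' @param step_size proposal width.
#' @param thin record every \code{thin}-th frame.
#' @return list of K \code{mc_trajectory} objects (one per ensemble), with a
#'   \code{swap_acceptance} attribute.
#' @export
replica_exchange_sample <- function(surface, schedule, n_steps,
                                    exchange_interval = 10L, seed = 1L,
                                    start = NULL, step_size = 0.12,
                                    thin = 1L) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(schedule, "bias_schedule"))
  K <- schedule$n_ensembles
  if (K < 2) stop("replica exchange needs at least two ensembles")
  if (exchange_interval < 1) stop("'exchange_interval' must be >= 1")
  if (is.null(start))
    start <- matrix(rep(surface$wells[1, 1:2], each = K), nrow = K)
  start <- matrix(as.numeric(start), nrow = K)
  la <- schedule$scaling * surface$flatten_alpha
  res <- .replica_exchange_cpp(unclass(surface), la, start,
                               as.integer(n_steps),
                               as.integer(exchange_interval), step_size,
                               as.numeric(seed), as.integer(thin))
  pos <- res$positions
  n_rec <- dim(pos)[1]
  out <- lapply(seq_len(K), function(k) {
    structure(list(positions = pos[, , k, drop = TRUE],
                   ensemble_labels = rep(k - 1L, n_rec),
                   acceptance_fraction = res$acceptance_fraction[k],
                   step_size = step_size, seed = seed,
                   thin = as.integer(thin),
                   lambda = schedule$scaling[k]),
              class = "mc_trajectory")
  })
  attr(out, "swap_acceptance") <- res$swap_acceptance
  out
}

#' Direct mean first-passage simulation to the dissociated state
#'
#' Simulates independent Metropolis walkers from \code{start} until the
#' distance from the channel mouth exceeds the surface's dissociation
#' threshold, without storing trajectories. The brute-force reference for
#' dissociation kinetics.
#'
#' @param surface a \code{potential_surface}.
#' @param n_events number of independent first-passage events.
#' @param start start coordinate (default: bound-well center).
#' @param step_size proposal width.
#' @param seed integer seed (event i uses stream seed + i).
#' @param max_steps per-event step cap; capped events return \code{NA}.
#' @return numeric vector of first-passage times in MC steps.
#' @export
sample_exit_times <- function(surface, n_events, start = NULL,
                              step_size = 0.12, seed = 1L,
                              max_steps = 5e7) {
  stopifnot(inherits(surface, "potential_surface"))
  if (is.null(start)) start <- surface$wells[1, 1:2]
  vapply(seq_len(n_events), function(i) {
    t <- .exit_time_cpp(unclass(surface), lambda_alpha(surface),
                        as.numeric(start), as.numeric(surface$mouth),
                        surface$dissociation_threshold, step_size,
                        as.numeric(seed) + i, max_steps)
    if (t < 0) NA_real_ else t
  }, numeric(1))
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "MC trajectory: %d frames (thin %d), ensemble %d, acceptance %.3f\n",
    nrow(x$positions), x$thin, x$ensemble_labels[1], x$acceptance_fraction))
  invisible(x)
}
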