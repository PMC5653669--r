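#' Forward committor probabilities
#'
#' Probability, per state, of reaching the target set B before the source
#' set A. Solves the committor linear system with boundary conditions
#' \eqn{q^+ = 0} on A and \eqn{q^+ = 1} on B; for reversible chains the
#' backward committor is \eqn{1 - q^+}.
#'
#' @param T a \code{transition_matrix} or plain row-stochastic matrix.
#' @param A,B disjoint, non-empty state index sets.
#' @return numeric vector of forward committor values in \eqn{[0, 1]}.
#' @export
committor <- function(T, A, B) {
  if (inherits(T, "transition_matrix")) T <- T$matrix
  check_sets(nrow(T), A, B)
  n <- nrow(T)
  q <- rep(0, n)
  q[B] <- 1
  C <- setdiff(seq_len(n), union(A, B))
  if (length(C)) {
    M <- diag(length(C)) - T[C, C, drop = FALSE]
    rhs <- rowSums(T[C, B, drop = FALSE])
    q[C] <- solve(M, rhs)
  }
  pmin(pmax(q, 0), 1)
}

#' Transition-path-theory reactive flux network
#'
#' Computes the equilibrium reactive flux of A-to-B transitions:
#' gross flux \eqn{f_{ij} = \pi_i (1 - q^+_i) T_{ij} q^+_j} for \eqn{i \ne j},
#' net flux \eqn{f^+_{ij} = \max(0, f_{ij} - f_{ji})}, the total A-to-B flux,
#' and the reaction rate \eqn{k_{AB} = F / (\tau \sum_i \pi_i (1 - q^+_i))}
#' in inverse physical time. Flux conservation at intermediate states and
#' equality of the net flux across independent cuts are verified before the
#' network is returned.
#'
#' @param T a \code{transition_matrix}.
#' @param A,B disjoint, non-empty state index sets.
#' @return a \code{flux_network} with fields \code{A}, \code{B},
#'   \code{committor}, \code{gross_flux}, \code{net_flux},
#'   \code{total_flux}, \code{rate_AB}, \code{stationary}, \code{lag}.
#' @export
reactive_flux <- function(T, A, B) {
  stopifnot(inherits(T, "transition_matrix"))
  qp <- committor(T, A, B)
  Tm <- T$matrix
  pi0 <- T$stationary
  n <- nrow(Tm)
  F <- (pi0 * (1 - qp)) %o% rep(1, n) * Tm * (rep(1, n) %o% qp)
  diag(F) <- 0
  Fnet <- pmax(F - t(F), 0)
  total <- sum(F[A, setdiff(seq_len(n), A), drop = FALSE])
  # conservation at intermediates and a second cut (into B)
  inter <- setdiff(seq_len(n), union(A, B))
  if (length(inter)) {
    imb <- abs(rowSums(Fnet)[inter] - colSums(Fnet)[inter])
    if (any(imb > 1e-10 * max(total, 1e-300)))
      stop("net-flux conservation violated at intermediate states")
  }
  total_B <- sum(Fnet[setdiff(seq_len(n), B), B, drop = FALSE])
  if (abs(total - total_B) > 1e-8 * max(total, 1e-300))
    stop("net flux differs across A/B cuts")
  rate <- if (total > 0) total / (T$lag * sum(pi0 * (1 - qp))) else 0
  structure(list(A = sort(A), B = sort(B), committor = qp, gross_flux = F,
                 net_flux = Fnet, total_flux = total, rate_AB = rate,
                 stationary = pi0, lag = T$lag),
            class = "flux_network")
}

# widest (maximum-bottleneck) path from any state in A to any state in B on
# the weighted graph W; lexicographic tie-break on state indices
widest_path <- function(W, A, B) {
  n <- nrow(W)
  width <- rep(-Inf, n)
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  width[A] <- Inf
  repeat {
    cand <- which(!done & width > 0)
    if (!length(cand)) break
    u <- cand[order(-width[cand], cand)][1]
    done[u] <- TRUE
    if (u %in% B) next
    for (v in which(W[u, ] > 0)) {
      w <- min(width[u], W[u, v])
      if (w > width[v] ||
          (w == width[v] && !is.na(pred[v]) && u < pred[v])) {
        width[v] <- w
        pred[v] <- u
      }
    }
  }
  reached <- B[is.finite(width[B]) & width[B] > 0]
  if (!length(reached)) return(NULL)
  end <- reached[order(-width[reached], reached)][1]
  path <- end
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  list(path = path, bottleneck = width[end])
}

#' Pathway decomposition of a reactive flux network
#'
#' Iteratively extracts the strongest pathway (the maximum-bottleneck path
#' on the net-flux graph, ties broken lexicographically on state indices),
#' subtracts its bottleneck flux along the path, and repeats until the
#' requested fraction of the total flux is covered. Numerically induced
#' cycles in the net flux (edges running against the committor ordering) are
#' pruned with a warning.
#'
#' @param fn a \code{flux_network}.
#' @param coverage target cumulative flux fraction in (0, 1].
#' @param max_paths safety cap on the number of extracted pathways.
#' @return a \code{pathway_decomposition}: list with \code{pathways} (list of
#'   state-index vectors), \code{path_fluxes}, \code{cumulative_fraction}.
#' @export
pathway_decomposition <- function(fn, coverage = 1.0, max_paths = 1000L) {
  stopifnot(inherits(fn, "flux_network"))
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must lie in (0, 1]")
  W <- fn$net_flux
  qp <- fn$committor
  bad <- which(W > 0 & outer(qp, qp, ">"), arr.ind = TRUE)
  if (nrow(bad)) {
    warning("pruned ", nrow(bad), " net-flux edge(s) against the committor ",
            "ordering")
    W[bad] <- 0
  }
  total <- fn$total_flux
  paths <- list()
  fluxes <- numeric(0)
  covered <- 0
  while (covered < coverage * total - 1e-14 * total &&
         length(paths) < max_paths) {
    wp <- widest_path(W, fn$A, fn$B)
    if (is.null(wp) || wp$bottleneck <= 0) break
    paths[[length(paths) + 1L]] <- wp$path
    fluxes <- c(fluxes, wp$bottleneck)
    covered <- covered + wp$bottleneck
    for (e in seq_len(length(wp$path) - 1L))
      W[wp$path[e], wp$path[e + 1L]] <-
        W[wp$path[e], wp$path[e + 1L]] - wp$bottleneck
  }
  structure(list(pathways = paths, path_fluxes = fluxes,
                 cumulative_fraction = cumsum(fluxes) / total,
                 total_flux = total),
            class = "pathway_decomposition")
}

#' Coarse-grain a flux network onto macrostates
#'
#' Sums net fluxes between groups of a state partition and
#' re-skew-symmetrizes, preserving the total A-to-B flux. A and B must map
#' into macrostates consistently (no macrostate may mix A/B members with
#' other roles in a way that splits the boundary).
#'
#' @param fn a \code{flux_network}.
#' @param macro_sets partition of all states: list of index vectors.
#' @return a \code{flux_network} over macrostates (committor is the
#'   stationary-weighted average per group).
#' @export
coarse_grain_flux <- function(fn, macro_sets) {
  stopifnot(inherits(fn, "flux_network"))
  n <- nrow(fn$net_flux)
  assign <- rep(NA_integer_, n)
  for (g in seq_along(macro_sets)) assign[macro_sets[[g]]] <- g
  if (any(is.na(assign))) stop("macro_sets must cover all states")
  if (any(table(unlist(macro_sets)) > 1)) stop("macro_sets must be disjoint")
  gA <- unique(assign[fn$A])
  gB <- unique(assign[fn$B])
  mixedA <- any(vapply(gA, function(g)
    any(!(which(assign == g) %in% fn$A)) &&
      any(which(assign == g) %in% fn$B), logical(1)))
  if (length(intersect(gA, gB)))
    stop("partition merges source and target states into one macrostate")
  if (isTRUE(mixedA)) stop("partition splits A/B inconsistently")
  G <- length(macro_sets)
  Fg <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in seq_len(G)) {
    if (a == b) next
    Fg[a, b] <- sum(fn$net_flux[macro_sets[[a]], macro_sets[[b]],
                                drop = FALSE])
  }
  Fnet <- pmax(Fg - t(Fg), 0)
  piM <- vapply(macro_sets, function(s) sum(fn$stationary[s]), numeric(1))
  qM <- vapply(macro_sets, function(s) {
    w <- fn$stationary[s]
    sum(w * fn$committor[s]) / sum(w)
  }, numeric(1))
  total <- sum(Fnet[gA, setdiff(seq_len(G), gA), drop = FALSE])
  structure(list(A = sort(gA), B = sort(gB), committor = qM,
                 gross_flux = Fg, net_flux = Fnet, total_flux = total,
                 rate_AB = fn$rate_AB, stationary = piM, lag = fn$lag,
                 macro_sets = macro_sets),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf(
    "flux network: %d states, total A->B flux %.4g, rate %.4g per time\n",
    nrow(x$net_flux), x$total_flux, x$rate_AB))
  invisible(x)
}

#' @export
print.pathway_decomposition <- function(x, ...) {
  cat(sprintf("pathway decomposition: %d pathway(s), %.1f%% of total flux\n",
              length(x$pathways),
              100 * (if (length(x$cumulative_fraction))
                tail(x$cumulative_fraction, 1) else 0)))
  for (i in seq_along(x$pathways))
    cat(sprintf("  %5.1f%%  %s\n", 100 * x$path_fluxes[i] / x$total_flux,
                paste(x$pathways[[i]], collapse = " -> ")))
  invisible(x)
}
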