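# Shared fixtures: hand-built count models, random reversible chains,
# feasible TRAMMBAR parameter probes, and small closed-form oracles.

mk_traj <- function(states, ensemble = 0L, role = "tram", bias = NULL) {
  structure(list(states = as.integer(states), ensemble = as.integer(ensemble),
                 role = role, stride = 1L, bias = bias),
            class = "discrete_trajectory")
}

mk_cm <- function(counts, trajs, lag = 1L) {
  if (length(dim(counts)) == 2) counts <- array(counts, c(dim(counts), 1L))
  K <- dim(counts)[3]
  n <- dim(counts)[1]
  ssc <- matrix(0, n, K)
  msc <- numeric(K)
  for (tr in trajs) {
    k <- tr$ensemble + 1L
    if (tr$role == "mbar") msc[k] <- msc[k] + length(tr$states)
    else ssc[, k] <- ssc[, k] + tabulate(tr$states, nbins = n)
  }
  structure(list(counts = counts, lag = as.integer(lag), n_states = n,
                 n_ensembles = K, state_sample_counts = ssc,
                 mbar_sample_counts = msc, mode = "sliding", trajs = trajs,
                 active = seq_len(n)),
            class = "count_model")
}

# counts of a simulated Markov chain trajectory
simulate_chain <- function(T, n_steps, start = 1L, seed = 1L) {
  set.seed(seed)
  n <- nrow(T)
  s <- integer(n_steps + 1L)
  s[1] <- start
  for (t in seq_len(n_steps))
    s[t + 1L] <- sample.int(n, 1L, prob = T[s[t], ])
  s
}

# random reversible transition matrix with stationary distribution
random_reversible <- function(n, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n * n, 0.05, 1), n)
  X <- X + t(X)
  list(T = X / rowSums(X), pi = rowSums(X) / sum(X))
}

# random TRAMMBAR-feasible parameter point for a count model:
# random positive mu -> f_ik from the normalization constraints ->
# Metropolis-reversible p^k w.r.t. e^{-f^k} (rows sum to 1 exactly)
random_feasible_params <- function(cm, seed = 1L) {
  set.seed(seed)
  dat <- memmtools:::memm_data(cm)
  n <- cm$n_states
  K <- cm$n_ensembles
  st <- c(dat$tram_state, dat$mbar_state)
  bias <- rbind(dat$tram_bias, dat$mbar_bias)
  N <- length(st)
  log_mu <- log(runif(N, 0.2, 1))
  log_mu <- log_mu - memmtools:::logsumexp(log_mu)
  f_ik <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    sel <- st == i
    for (k in seq_len(K))
      f_ik[i, k] <- -memmtools:::logsumexp(log_mu[sel] - bias[sel, k])
  }
  p <- lapply(seq_len(K), function(k) {
    pi_k <- exp(-(f_ik[, k] - min(f_ik[, k])))
    A <- matrix(runif(n * n, 0.1, 1), n)
    A <- (A + t(A)) / (4 * n)            # symmetric sub-stochastic proposal
    P <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      P[i, j] <- A[i, j] * min(1, pi_k[j] / pi_k[i])
    }
    diag(P) <- 1 - rowSums(P)
    P
  })
  list(f_ik = f_ik, p = p, log_mu = log_mu)
}

# exhaustive grid-search oracle for the 2-state reversible MSM likelihood
grid_search_2state <- function(C, n_grid = 201L) {
  best <- list(ll = -Inf)
  for (pi1 in seq(0.005, 0.995, length.out = n_grid)) {
    pi <- c(pi1, 1 - pi1)
    # reversible: p12 free in (0, min(1, pi2/pi1)], p21 = pi1 p12 / pi2
    pmax12 <- min(1, pi[2] / pi[1])
    for (p12 in seq(pmax12 / n_grid, pmax12, length.out = n_grid)) {
      p21 <- pi[1] * p12 / pi[2]
      if (p21 > 1) next
      P <- matrix(c(1 - p12, p12, p21, 1 - p21), 2, byrow = TRUE)
      if (any(P < 0)) next
      ll <- sum(C[C > 0] * log(P[C > 0]))
      if (ll > best$ll) best <- list(ll = ll, P = P, pi = pi)
    }
  }
  best
}

# gambler's-ruin (resistor) committor for a birth-death chain
birth_death_committor <- function(p_up, p_down) {
  n <- length(p_up) + 1L
  rho <- cumprod(c(1, p_down[-1] / p_up[-1]))
  q <- c(0, cumsum(rho) / sum(rho))
  q
}

# small landscape with shallow wells for cheap sampling tests
fast_landscape <- function() {
  build_default_landscape(list(
    wells = rbind(bound = c(-1.7, 0, 5.0, 0.35),
                  prebound = c(-0.4, 0, 3.0, 0.30),
                  misbound1 = c(0.45, 2, 2.5, 0.45),
                  misbound2 = c(0.45, -2, 2.0, 0.45))))
}
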